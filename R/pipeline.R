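#' End-to-end cross-link evaluation run
#'
#' Orchestrates the pipeline stages over a configuration list: distance
#' budgets, cross-link mapping and satisfaction on the receptor-ligand
#' assembly at each pose, restraint/clash filtering, truncation to the
#' best `n_keep`, Ward clustering with medoid representatives, and
#' (optionally) trajectory analyses. Every intermediate is written as
#' delimited text under `output_dir`, plus a single structured JSON
#' summary; reruns with an identical config are bit-reproducible (all
#' randomness flows from `cfg$seed`).
#'
#' The defaults mirror standard CL-MS-guided docking practice: at least 3
#' satisfied restraints, zero tolerated clashes, pose list cut to 30, and
#' 3 clusters.
#'
#' @param cfg a [run_config()] list.
#' @return list of class `xl_run_report` with per-stage results.
#' @export
run_xl_eval <- function(cfg) {
  cfg <- validate_config(cfg)
  out <- cfg$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  report <- list(config = cfg[setdiff(names(cfg), c("receptor", "ligand",
                                                    "poses", "links",
                                                    "trajectory", "core"))])

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage:%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  links <- stage("links", {
    if (!is.null(cfg$links)) cfg$links
    else read_crosslink_table(cfg$crosslink_table, cfg$registry)
  })
  report$budgets <- stage("budgets", {
    data.frame(linker = unique(links$linker),
               budget = vapply(unique(links$linker), distance_budget, 0,
                               registry = cfg$registry))
  })
  utils::write.table(report$budgets, file.path(out, "budgets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  receptor <- stage("structures", {
    if (!is.null(cfg$receptor)) cfg$receptor
    else as_assembly(read_structure(cfg$receptor_pdb))
  })
  ligand <- stage("structures", {
    if (!is.null(cfg$ligand)) cfg$ligand
    else as_assembly(read_structure(cfg$ligand_pdb))
  })
  poses <- stage("poses", {
    if (!is.null(cfg$poses)) cfg$poses
    else read_pose_list(cfg$pose_list)
  })

  scores <- stage("score", {
    lapply(poses, function(p) {
      score_pose(p, receptor, ligand, links,
                 receptor_proteins = cfg$receptor_proteins,
                 ligand_proteins = cfg$ligand_proteins,
                 core = cfg$core, offsets = cfg$offsets,
                 min_satisfied = cfg$min_satisfied,
                 max_clash = cfg$max_clash,
                 clash_cutoff = cfg$clash_cutoff,
                 registry = cfg$registry)
    })
  })
  report$scores <- pose_score_table(scores)
  report$satisfaction <- stage("satisfaction", {
    best <- which.max(report$scores$n_satisfied)
    evaluate_satisfaction(scores[[best]]$mapping)
  })
  write_satisfaction_report(report$satisfaction,
                            file.path(out, "satisfaction_best_pose.tsv"))

  report$passed <- stage("filter", {
    filter_poses(report$scores, cfg$min_satisfied, cfg$max_clash)
  })
  report$kept <- stage("truncate", {
    keep <- report$scores[report$scores$pose_id %in% report$passed, ,
                          drop = FALSE]
    truncate_pose_list(keep, cfg$n_keep)
  })

  report$clusters <- stage("cluster", {
    if (length(report$kept) >= max(2L, cfg$k_clusters)) {
      kept_poses <- poses[match(report$kept,
                                vapply(poses, `[[`, "", "pose_id"))]
      feats <- featurize_poses(kept_poses, ligand)
      ward_cluster(feats, cfg$k_clusters)
    } else NULL
  })
  write_pose_report(report$scores, file.path(out, "pose_scores.tsv"),
                    clusters = report$clusters)

  if (!is.null(cfg$trajectory)) {
    traj <- cfg$trajectory
    report$analyses <- stage("traj", {
      res <- list()
      if (isTRUE(cfg$analyses$rmsd)) {
        res$rmsd <- rmsd_series(traj)
        utils::write.table(data.frame(frame = seq_along(res$rmsd),
                                      rmsd = res$rmsd),
                           file.path(out, "rmsd.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
      if (isTRUE(cfg$analyses$rmsf)) {
        res$rmsf <- rmsf(traj)
        utils::write.table(data.frame(atom = names(res$rmsf),
                                      rmsf = unname(res$rmsf)),
                           file.path(out, "rmsf.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
      if (isTRUE(cfg$analyses$q)) {
        contacts <- native_contacts(traj)
        res$q <- q_series(traj, contacts)
        utils::write.table(data.frame(frame = seq_along(res$q), q = res$q),
                           file.path(out, "q.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
      if (isTRUE(cfg$analyses$pca)) {
        res$pca <- pca_projection(traj)
        utils::write.table(data.frame(frame = seq_len(nrow(res$pca$projections)),
                                      res$pca$projections),
                           file.path(out, "pca_projections.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
      res
    })
  }

  summary <- list(
    n_links = nrow(links),
    n_poses = length(poses),
    n_passed = length(report$passed),
    n_kept = length(report$kept),
    best_pose = report$scores$pose_id[which.max(report$scores$n_satisfied)],
    n_satisfied_best = max(report$scores$n_satisfied),
    k_clusters = if (!is.null(report$clusters)) report$clusters$k else 0L,
    representatives = if (!is.null(report$clusters))
      unname(report$clusters$representatives) else character(0),
    seed = cfg$seed
  )
  jsonlite::write_json(summary, file.path(out, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report$summary <- summary
  class(report) <- "xl_run_report"
  report
}

#' @export
print.xl_run_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<xl_run_report> %d poses scored, %d passed (>= %d restraints, <= %d clashes), %d kept; best pose %s (%d/%d links)\n",
              s$n_poses, s$n_passed, x$config$min_satisfied,
              x$config$max_clash, s$n_kept, s$best_pose,
              s$n_satisfied_best, x$satisfaction$n_mappable))
  invisible(x)
}

#' Pipeline run configuration
#'
#' In-memory objects (`receptor`, `ligand`, `poses`, `links`,
#' `trajectory`, `core`) take precedence over the corresponding file paths
#' (`receptor_pdb`, `ligand_pdb`, `pose_list`, `crosslink_table`).
#'
#' @param receptor_proteins,ligand_proteins protein names (as used in the
#'   cross-link table) carried by the receptor and the ligand.
#' @param min_satisfied restraint-count threshold (default 3).
#' @param max_clash clash tolerance (default 0).
#' @param clash_cutoff CA-CA clash distance, Angstrom (default 3.0).
#' @param n_keep pose-list truncation length (default 30).
#' @param k_clusters Ward cluster count (default 3).
#' @param output_dir where intermediates are written.
#' @param seed seed governing any stochastic stage.
#' @param ... further fields: `receptor`, `ligand`, `core`, `poses`,
#'   `links`, `trajectory`, `receptor_pdb`, `ligand_pdb`, `pose_list`,
#'   `crosslink_table`, `offsets`, `registry`, `analyses` (named list of
#'   logical toggles: rmsd, rmsf, q, pca). All arguments must be given by
#'   (full) name.
#' @export
run_config <- function(..., receptor_proteins = NULL, ligand_proteins = NULL,
                       min_satisfied = 3L, max_clash = 0L,
                       clash_cutoff = 3.0, n_keep = 30L, k_clusters = 3L,
                       output_dir = tempfile("xlrun"), seed = 1L) {
  cfg <- c(list(receptor_proteins = receptor_proteins,
                ligand_proteins = ligand_proteins,
                min_satisfied = min_satisfied, max_clash = max_clash,
                clash_cutoff = clash_cutoff, n_keep = n_keep,
                k_clusters = k_clusters, output_dir = output_dir,
                seed = seed),
           list(...))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  defaults <- list(min_satisfied = 3L, max_clash = 0L, clash_cutoff = 3.0,
                   n_keep = 30L, k_clusters = 3L, seed = 1L,
                   registry = default_linkers(), offsets = NULL, core = NULL,
                   analyses = list(rmsd = TRUE, rmsf = TRUE, q = FALSE,
                                   pca = FALSE))
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (is.null(cfg$output_dir)) cfg$output_dir <- tempfile("xlrun")
  if (is.null(cfg$receptor_proteins) || is.null(cfg$ligand_proteins)) {
    stop("run config: receptor_proteins and ligand_proteins are required")
  }
  if (is.null(cfg$links) && is.null(cfg$crosslink_table)) {
    stop("run config: either links or crosslink_table is required")
  }
  if (!is.null(cfg$crosslink_table) && is.null(cfg$links) &&
      !file.exists(cfg$crosslink_table)) {
    stop("run config: cross-link table not found: ", cfg$crosslink_table)
  }
  if (is.null(cfg$poses) && is.null(cfg$pose_list)) {
    stop("run config: either poses or pose_list is required")
  }
  cfg
}
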