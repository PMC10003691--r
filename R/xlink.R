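#' Linker chemistries and distance budgets
#'
#' A cross-linker is described by its spacer length plus two geometric
#' allowances: the reach of the two Lys side chains (5.5 Angstrom each) and
#' an extra allowance for backbone dynamics (7.6 Angstrom). The maximum
#' CA-CA distance compatible with a cross-link — its distance budget — is
#'
#'   budget = spacer + 2 x side-chain allowance + dynamics allowance.
#'
#' The two built-in chemistries are the carbonyl-diimidazole linker CDI
#' (spacer 2.6 A, budget 21.2 A) and the urea-based linker DSBU (spacer
#' 12.5 A, budget 31.1 A).
#'
#' @param name linker name.
#' @param spacer_length spacer arm length, Angstrom.
#' @param sidechain_allowance per-residue Lys side-chain allowance, Angstrom.
#' @param dynamics_allowance backbone-dynamics allowance, Angstrom.
#' @param reactive_targets residue names the chemistry reacts with.
#' @return An object of class `xl_linker`.
#' @export
linker_chemistry <- function(name, spacer_length,
                             sidechain_allowance = 5.5,
                             dynamics_allowance = 7.6,
                             reactive_targets = "LYS") {
  vals <- c(spacer_length, sidechain_allowance, dynamics_allowance)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("linker_chemistry: lengths must be finite and >= 0")
  }
  structure(list(name = name, spacer_length = spacer_length,
                 sidechain_allowance = sidechain_allowance,
                 dynamics_allowance = dynamics_allowance,
                 reactive_targets = reactive_targets),
            class = "xl_linker")
}

#' Default linker registry
#'
#' @return named list of `xl_linker` objects with entries `CDI` and `DSBU`.
#' @export
default_linkers <- function() {
  list(
    CDI = linker_chemistry("CDI", spacer_length = 2.6),
    DSBU = linker_chemistry("DSBU", spacer_length = 12.5)
  )
}

#' Maximum CA-CA distance budget of a linker
#'
#' @param chem an `xl_linker`, or a linker name resolved in `registry`.
#' @param registry named list of linkers (default [default_linkers()]).
#' @return budget in Angstrom: spacer + 2 x side chain + dynamics.
#' @export
distance_budget <- function(chem, registry = default_linkers()) {
  if (is.character(chem)) {
    if (!chem %in% names(registry)) {
      stop("distance_budget: unregistered linker: ", chem)
    }
    chem <- registry[[chem]]
  }
  stopifnot(inherits(chem, "xl_linker"))
  chem$spacer_length + 2 * chem$sidechain_allowance + chem$dynamics_allowance
}

#' Cross-link identification tables
#'
#' One row per identified link: `protein_a`, `res_a`, `protein_b`, `res_b`,
#' `linker`, optional `score`. Comma- or tab-delimited with a header (the
#' delimiter is sniffed). Residue numbers follow the precursor protein
#' sequence; an offset map reconciles them with model numbering at mapping
#' time.
#'
#' @param path delimited text file.
#' @param registry linker registry used to validate linker names.
#' @return data frame of class `xl_crosslinks` with a `source_row`
#'   provenance column.
#' @export
read_crosslink_table <- function(path, registry = default_linkers()) {
  if (!file.exists(path)) stop("read_crosslink_table: file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  crosslink_table(tab, registry = registry,
                  source = paste0(basename(path), ":", seq_len(nrow(tab)) + 1L))
}

#' @param df data frame with the required columns.
#' @param source provenance strings, one per row.
#' @rdname read_crosslink_table
#' @export
crosslink_table <- function(df, registry = default_linkers(), source = NULL) {
  req <- c("protein_a", "res_a", "protein_b", "res_b", "linker")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("crosslink_table: missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  res_a <- suppressWarnings(as.integer(df$res_a))
  res_b <- suppressWarnings(as.integer(df$res_b))
  bad <- which(is.na(res_a) | is.na(res_b) | res_a < 1L | res_b < 1L)
  if (length(bad)) {
    where <- if (!is.null(source)) source[bad[1]] else paste("row", bad[1])
    stop("crosslink_table: unparseable or out-of-range residue number at ",
         where)
  }
  unknown <- setdiff(unique(df$linker), names(registry))
  if (length(unknown)) {
    stop("crosslink_table: unregistered linker(s): ",
         paste(unknown, collapse = ", "))
  }
  out <- data.frame(
    protein_a = as.character(df$protein_a), res_a = res_a,
    protein_b = as.character(df$protein_b), res_b = res_b,
    linker = as.character(df$linker),
    score = if ("score" %in% names(df)) as.numeric(df$score) else NA_real_,
    source_row = if (!is.null(source)) source else
      if ("source_row" %in% names(df)) df$source_row else
      paste0("row", seq_len(nrow(df))),
    stringsAsFactors = FALSE
  )
  class(out) <- c("xl_crosslinks", "data.frame")
  out
}

#' @param links an `xl_crosslinks` table.
#' @rdname read_crosslink_table
#' @export
write_crosslink_table <- function(links, path) {
  utils::write.table(as.data.frame(links)[, c("protein_a", "res_a",
                                              "protein_b", "res_b",
                                              "linker", "score")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map cross-links onto an assembly
#'
#' For every link, all cross-copy candidate chain pairs are enumerated (a
#' link between two copies of the same protein in a homo-oligomer is
#' ambiguous: the identified peptide pair cannot tell which copies
#' reacted). The mapped distance is the minimum CA-CA distance over all
#' candidate pairs — the most charitable placement, matching how restraints
#' on symmetric assemblies are evaluated. Links to residues absent from the
#' model are flagged unmappable and carried through to the report.
#'
#' @param a an `xl_assembly`.
#' @param links an `xl_crosslinks` table.
#' @param chain_assignment named list: protein name -> character vector of
#'   assembly chain labels carrying that protein.
#' @param offsets optional named numeric: protein name -> integer added to
#'   the table's residue numbers to obtain model numbering.
#' @param registry linker registry.
#' @return data frame of class `xl_mapping`: one row per link with
#'   `min_distance`, `n_candidates`, `budget`, `mappable`, `satisfied`, and
#'   a `candidates` attribute holding the per-pair distances.
#' @export
map_crosslinks <- function(a, links, chain_assignment, offsets = NULL,
                           registry = default_linkers()) {
  stopifnot(inherits(a, "xl_assembly"))
  links <- if (inherits(links, "xl_crosslinks")) links else crosslink_table(links, registry)
  prots <- unique(c(links$protein_a, links$protein_b))
  missing_assign <- setdiff(prots, names(chain_assignment))
  if (length(missing_assign)) {
    stop("map_crosslinks: no chain assignment for protein(s): ",
         paste(missing_assign, collapse = ", "))
  }
  known <- unique(a$atoms$chain_label)
  for (p in prots) {
    bad <- setdiff(chain_assignment[[p]], known)
    if (length(bad)) {
      stop("map_crosslinks: chain label(s) not in assembly: ",
           paste(bad, collapse = ", "))
    }
  }
  off <- function(p) if (!is.null(offsets) && p %in% names(offsets)) offsets[[p]] else 0L

  ca <- a$atoms$atom_name == "CA"
  ca_key <- paste(a$atoms$chain_label, a$atoms$seq_num)
  ca_idx <- stats::setNames(which(ca), ca_key[ca])

  candidates <- vector("list", nrow(links))
  min_d <- rep(NA_real_, nrow(links))
  n_cand <- integer(nrow(links))
  budget <- vapply(links$linker, distance_budget, 0, registry = registry)

  for (i in seq_len(nrow(links))) {
    ra <- links$res_a[i] + off(links$protein_a[i])
    rb <- links$res_b[i] + off(links$protein_b[i])
    ch_a <- chain_assignment[[links$protein_a[i]]]
    ch_b <- chain_assignment[[links$protein_b[i]]]
    grid <- expand.grid(chain_a = ch_a, chain_b = ch_b,
                        stringsAsFactors = FALSE)
    # drop the degenerate pairing of a residue with itself
    grid <- grid[!(grid$chain_a == grid$chain_b & ra == rb), , drop = FALSE]
    ia <- ca_idx[paste(grid$chain_a, ra)]
    ib <- ca_idx[paste(grid$chain_b, rb)]
    ok <- !is.na(ia) & !is.na(ib)
    grid <- grid[ok, , drop = FALSE]
    if (nrow(grid)) {
      d <- sqrt(rowSums((a$coords[ia[ok], , drop = FALSE] -
                         a$coords[ib[ok], , drop = FALSE])^2))
      # dedupe unordered chain pairs for same-protein links
      pair_key <- ifelse(grid$chain_a < grid$chain_b,
                         paste(grid$chain_a, grid$chain_b, ra, rb),
                         paste(grid$chain_b, grid$chain_a, rb, ra))
      keep <- !duplicated(pair_key)
      grid <- grid[keep, , drop = FALSE]
      d <- d[keep]
      candidates[[i]] <- data.frame(grid, distance = d,
                                    stringsAsFactors = FALSE)
      min_d[i] <- min(d)
      n_cand[i] <- length(d)
    } else {
      candidates[[i]] <- data.frame(chain_a = character(),
                                    chain_b = character(),
                                    distance = numeric())
    }
  }

  out <- data.frame(
    links,
    budget = budget,
    n_candidates = n_cand,
    min_distance = min_d,
    mappable = n_cand > 0L,
    satisfied = !is.na(min_d) & min_d <= budget,
    stringsAsFactors = FALSE
  )
  attr(out, "candidates") <- candidates
  class(out) <- c("xl_mapping", "data.frame")
  out
}

#' Summarise cross-link satisfaction
#'
#' Counts links whose minimum-over-copies CA-CA distance falls within the
#' linker's budget (inclusive comparison, matching the "up to" phrasing of
#' the budgets). Unmappable links are excluded from the denominator by
#' default but always listed; set `count_unmappable = TRUE` to count them
#' in the denominator.
#'
#' @param mapping an `xl_mapping` from [map_crosslinks()].
#' @param count_unmappable include unmappable links in the denominator?
#' @return list of class `xl_satisfaction` with `n_total`, `n_mappable`,
#'   `n_satisfied`, the per-link table, and the denominator convention.
#' @export
evaluate_satisfaction <- function(mapping, count_unmappable = FALSE) {
  stopifnot(inherits(mapping, "xl_mapping"))
  rep <- list(
    n_total = nrow(mapping),
    n_mappable = sum(mapping$mappable),
    n_satisfied = sum(mapping$satisfied),
    denominator = if (count_unmappable) nrow(mapping) else sum(mapping$mappable),
    per_link = mapping
  )
  class(rep) <- "xl_satisfaction"
  rep
}

#' @export
print.xl_satisfaction <- function(x, ...) {
  cat(sprintf("<xl_satisfaction> %d of %d mappable cross-links within budget (%d total)\n",
              x$n_satisfied, x$denominator, x$n_total))
  invisible(x)
}

#' Write a satisfaction report as delimited text
#'
#' One row per link with all candidate distances (semicolon-joined), the
#' minimum distance, the budget and the satisfaction flag.
#'
#' @param report an `xl_satisfaction`.
#' @param path output path.
#' @export
write_satisfaction_report <- function(report, path) {
  m <- report$per_link
  cand <- attr(m, "candidates")
  tab <- data.frame(
    as.data.frame(m)[, c("protein_a", "res_a", "protein_b", "res_b", "linker")],
    candidate_distances = vapply(cand, function(cc) {
      paste(sprintf("%.3f", cc$distance), collapse = ";")
    }, ""),
    min_distance = round(m$min_distance, 3),
    budget = m$budget,
    mappable = m$mappable,
    satisfied = m$satisfied
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
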