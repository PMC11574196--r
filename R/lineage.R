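#' Build a pedigree tree from tracked cell records
#'
#' Derives the parent-child structure of a tracked population from per-cell
#' records. Each cell must have a single, constant parent id (NA for a
#' root); parent references must resolve to cells present in the table.
#'
#' @param records A data frame with `cell_id` and `parent_id` columns (one
#'   or more rows per cell; `frame` is used for birth frames when present).
#' @return An object of class `pedigree`: list with `nodes` (tibble
#'   `cell_id`, `parent_id`, `birth_frame`, `depth`), `roots` (ids with no
#'   parent) and `n_cells`. More than one root is allowed (mixed
#'   field-of-view) but flagged with a warning.
#' @export
build_tree <- function(records) {
  stopifnot(all(c("cell_id", "parent_id") %in% names(records)))
  nodes <- dplyr::summarise(
    dplyr::group_by(records, .data$cell_id),
    n_parents = dplyr::n_distinct(.data$parent_id),
    parent_id = unique(.data$parent_id)[1],
    birth_frame = if ("frame" %in% names(records))
      min(.data$frame) else NA_integer_,
    .groups = "drop"
  )
  if (any(nodes$n_parents > 1L)) {
    stop("Cell(s) with multiple parents: ",
         paste(nodes$cell_id[nodes$n_parents > 1L], collapse = ", "))
  }
  nodes$n_parents <- NULL
  known <- nodes$cell_id
  orphan <- !is.na(nodes$parent_id) & !(nodes$parent_id %in% known)
  if (any(orphan)) {
    stop("Parent id(s) not present in the records: ",
         paste(unique(nodes$parent_id[orphan]), collapse = ", "))
  }
  # depth by iterative propagation; failure to resolve implies a cycle
  depth <- ifelse(is.na(nodes$parent_id), 0L, NA_integer_)
  names(depth) <- as.character(nodes$cell_id)
  for (i in seq_len(nrow(nodes) + 1L)) {
    todo <- is.na(depth)
    if (!any(todo)) break
    pd <- depth[as.character(nodes$parent_id[todo])]
    depth[todo] <- ifelse(is.na(pd), NA_integer_, pd + 1L)
    if (i > nrow(nodes)) stop("Cycle detected in parent links.")
  }
  if (any(is.na(depth))) stop("Cycle detected in parent links.")
  nodes$depth <- as.integer(depth)
  roots <- nodes$cell_id[is.na(nodes$parent_id)]
  if (length(roots) == 0L) stop("No root cell found.")
  if (length(roots) > 1L) {
    warning(length(roots), " roots found (mixed field-of-view?): ",
            paste(roots, collapse = ", "))
  }
  structure(list(nodes = nodes, roots = roots, n_cells = nrow(nodes)),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat("<pedigree>", x$n_cells, "cells,", length(x$roots), "root(s), max depth",
      max(x$nodes$depth), "\n")
  invisible(x)
}

#' h value of each cell at a matched growth stage
#'
#' To compare heteroplasmy across cells at an equivalent cell-cycle point,
#' each cell is sampled at the first frame where its bud-to-mother volume
#' ratio reaches `target_ratio` (inclusive; default 20%). Cells that never
#' reach the ratio are excluded.
#'
#' @param h_table A data frame with `cell_id`, `frame`, `bud_ratio` and `h`
#'   columns (e.g. [add_h_values()] output).
#' @param target_ratio Bud-to-mother volume ratio defining the stage.
#' @return A tibble with one row per qualifying cell: `cell_id`,
#'   `stage_frame`, `h`.
#' @export
stage_matched_h <- function(h_table, target_ratio = 0.2) {
  stopifnot(all(c("cell_id", "frame", "bud_ratio", "h") %in% names(h_table)))
  qual <- h_table[!is.na(h_table$bud_ratio) &
                    h_table$bud_ratio >= target_ratio & !is.na(h_table$h), ]
  if (nrow(qual) == 0L) {
    return(tibble::tibble(cell_id = qual$cell_id,
                          stage_frame = integer(0), h = numeric(0)))
  }
  out <- dplyr::summarise(
    dplyr::group_by(qual, .data$cell_id),
    stage_frame = min(.data$frame),
    .groups = "drop"
  )
  out <- dplyr::left_join(
    out, h_table[, c("cell_id", "frame", "h")],
    by = c("cell_id", "stage_frame" = "frame")
  )
  out
}

#' Mother-progeny heteroplasmy pairs at matched growth stages
#'
#' Builds the four relation pair sets used to probe partitioning asymmetry:
#' mother vs daughter (`M-D`), mother vs granddaughter (`M-GD`), and the
#' mother compared with herself at the daughter's / granddaughter's stage
#' time (`M-M_D`, `M-M_GD`). The mother's own h is taken at the first frame
#' where she reaches the bud-ratio stage; D and GD at their own stage
#' frames; `M_D` and `M_GD` are the mother's h at those same frames.
#'
#' @param h_table A data frame with `cell_id`, `parent_id`, `frame`,
#'   `bud_ratio`, `h`.
#' @param target_ratio Growth-stage bud ratio (default 0.2).
#' @return A tibble with `relation` (factor M-D, M-GD, M-M_D, M-M_GD),
#'   `mother_id`, `other_id`, `h_first` (mother at her own stage),
#'   `h_second`.
#' @export
relation_pairs <- function(h_table, target_ratio = 0.2) {
  tree <- build_tree(h_table)
  stage <- stage_matched_h(h_table, target_ratio)
  nodes <- tree$nodes
  h_at <- function(cells, frames) {
    idx <- match(paste(cells, frames), paste(h_table$cell_id, h_table$frame))
    h_table$h[idx]
  }
  kids <- nodes[!is.na(nodes$parent_id), c("cell_id", "parent_id")]
  # daughters with a stage frame, whose mother also has one
  d <- dplyr::inner_join(kids, stage, by = "cell_id")
  names(d) <- c("other_id", "mother_id", "stage_frame", "h_second")
  m_stage <- stats::setNames(stage$h, stage$cell_id)
  d$h_first <- unname(m_stage[as.character(d$mother_id)])
  md <- d[!is.na(d$h_first), ]
  rows <- list()
  if (nrow(md) > 0L) {
    rows$md <- tibble::tibble(relation = "M-D", mother_id = md$mother_id,
                              other_id = md$other_id, h_first = md$h_first,
                              h_second = md$h_second)
    mmd_h <- h_at(md$mother_id, md$stage_frame)
    keep <- !is.na(mmd_h)
    rows$mmd <- tibble::tibble(relation = "M-M_D",
                               mother_id = md$mother_id[keep],
                               other_id = md$mother_id[keep],
                               h_first = md$h_first[keep],
                               h_second = mmd_h[keep])
  }
  # granddaughters: children of the daughters
  gd <- dplyr::inner_join(kids, kids, by = c("parent_id" = "cell_id"),
                          suffix = c("", "_grand"))
  # gd: cell_id = granddaughter, parent_id = daughter, parent_id_grand = mother
  gd <- dplyr::inner_join(gd, stage, by = "cell_id")
  gd$h_first <- unname(m_stage[as.character(gd$parent_id_grand)])
  gd <- gd[!is.na(gd$h_first), ]
  if (nrow(gd) > 0L) {
    rows$mgd <- tibble::tibble(relation = "M-GD",
                               mother_id = gd$parent_id_grand,
                               other_id = gd$cell_id, h_first = gd$h_first,
                               h_second = gd$h)
    mmgd_h <- h_at(gd$parent_id_grand, gd$stage_frame)
    keep <- !is.na(mmgd_h)
    rows$mmgd <- tibble::tibble(relation = "M-M_GD",
                                mother_id = gd$parent_id_grand[keep],
                                other_id = gd$parent_id_grand[keep],
                                h_first = gd$h_first[keep],
                                h_second = mmgd_h[keep])
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(relation = factor(character(),
                                            levels = c("M-D", "M-GD",
                                                       "M-M_D", "M-M_GD")),
                          mother_id = integer(), other_id = integer(),
                          h_first = numeric(), h_second = numeric()))
  }
  out$relation <- factor(out$relation,
                         levels = c("M-D", "M-GD", "M-M_D", "M-M_GD"))
  out
}

#' Per-population rank correlation of relation pairs
#'
#' Spearman rank correlation (average ranks for ties) between `h_first` and
#' `h_second`, computed per population and relation. Populations with fewer
#' than 3 pairs for a relation, or with a constant vector (correlation
#' undefined), are dropped with a warning.
#'
#' @param pairs A data frame with `relation`, `h_first`, `h_second` and a
#'   population identifier column.
#' @param population Name of the population column (default
#'   `"population"`).
#' @param method Correlation method (default `"spearman"`).
#' @return A tibble with `population`, `relation`, `n_pairs`, `rho`.
#' @export
relation_correlation <- function(pairs, population = "population",
                                 method = "spearman") {
  stopifnot(all(c("relation", "h_first", "h_second", population) %in%
                  names(pairs)))
  out <- dplyr::summarise(
    dplyr::group_by(pairs, .data[[population]], .data$relation),
    n_pairs = dplyr::n(),
    rho = if (dplyr::n() < 3L ||
              stats::sd(.data$h_first) == 0 ||
              stats::sd(.data$h_second) == 0) NA_real_
    else stats::cor(.data$h_first, .data$h_second, method = method),
    .groups = "drop"
  )
  if (anyNA(out$rho)) {
    warning(sum(is.na(out$rho)),
            " population x relation cell(s) dropped: fewer than 3 pairs or",
            " constant h vector.")
    out <- out[!is.na(out$rho), ]
  }
  out
}

#' Paired comparison of relation correlations across populations
#'
#' Two-sided paired t-test on per-population correlation coefficients of
#' two relations (e.g. is the mother more similar to her later self,
#' `M-M_D`, than to her daughter, `M-D`?). Populations missing either
#' relation are dropped (pairwise-complete).
#'
#' @param coefficients Output of [relation_correlation()].
#' @param relation_a,relation_b Relation labels to compare.
#' @param population Name of the population column.
#' @return A one-row tibble: `relation_a`, `relation_b`, `n_populations`,
#'   `mean_a`, `mean_b`, `t`, `p_value`. A zero-variance difference yields
#'   `t = 0`, `p = 1` with a warning (flagged, not an error).
#' @export
compare_relations <- function(coefficients, relation_a, relation_b,
                              population = "population") {
  a <- coefficients[coefficients$relation == relation_a, ]
  b <- coefficients[coefficients$relation == relation_b, ]
  common <- intersect(a[[population]], b[[population]])
  if (length(common) < 2L) {
    stop("Need at least 2 populations with both relations; found ",
         length(common), ".")
  }
  va <- a$rho[match(common, a[[population]])]
  vb <- b$rho[match(common, b[[population]])]
  diff <- va - vb
  if (stats::sd(diff) == 0) {
    warning("Zero-variance paired difference; returning t = 0, p = 1.")
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(va, vb, paired = TRUE)
  }
  tibble::tibble(relation_a = relation_a, relation_b = relation_b,
                 n_populations = length(common),
                 mean_a = mean(va), mean_b = mean(vb),
                 t = unname(tt$statistic), p_value = tt$p.value)
}
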