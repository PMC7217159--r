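#' Construct a longitudinal cluster randomized trial design
#'
#' A trial design is a binary treatment schematic with one row per treatment
#' sequence and one column per period, together with the number of clusters
#' assigned to each sequence and the (constant) number of participants
#' measured in each cluster in each period.
#'
#' @param schematic Integer or numeric matrix of treatment indicators, S
#'   sequences by T periods, entries 0 (control) or 1 (intervention).
#' @param clusters_per_sequence Positive integer vector of length S giving the
#'   number of clusters assigned to each sequence. Defaults to one cluster per
#'   sequence. A scalar is recycled.
#' @param m Number of participants measured in each cluster in each period
#'   (positive integer).
#' @param label Optional free-text label for printing.
#'
#' @return An object of class `trial_design`: a list with elements
#'   `schematic`, `clusters_per_sequence`, `m`, `label`, `S`, `T` and the total
#'   number of clusters `K`.
#'
#' @examples
#' d <- trial_design(rbind(c(0, 1), c(1, 0)), clusters_per_sequence = 3, m = 8)
#' d$K
#' @export
trial_design <- function(schematic, clusters_per_sequence = NULL, m = 1,
                         label = "") {
  schematic <- as.matrix(schematic)
  if (!all(schematic %in% c(0, 1))) {
    stop("invalid-design: schematic entries must all be 0 or 1", call. = FALSE)
  }
  storage.mode(schematic) <- "integer"
  S <- nrow(schematic)
  T <- ncol(schematic)
  if (T < 2L) stop("invalid-design: at least two periods required", call. = FALSE)
  if (S < 1L) stop("invalid-design: at least one sequence required", call. = FALSE)
  if (is.null(clusters_per_sequence)) clusters_per_sequence <- rep(1L, S)
  if (length(clusters_per_sequence) == 1L) {
    clusters_per_sequence <- rep(clusters_per_sequence, S)
  }
  clusters_per_sequence <- as.integer(clusters_per_sequence)
  if (length(clusters_per_sequence) != S || any(clusters_per_sequence < 1L)) {
    stop("invalid-design: clusters_per_sequence must have one entry >= 1 per sequence",
         call. = FALSE)
  }
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 1L) {
    stop("invalid-design: m must be a positive integer", call. = FALSE)
  }
  dimnames(schematic) <- list(
    paste0("sequence_", seq_len(S)),
    paste0("period_", seq_len(T))
  )
  structure(
    list(schematic = schematic,
         clusters_per_sequence = clusters_per_sequence,
         m = m, label = label,
         S = S, T = T, K = sum(clusters_per_sequence)),
    class = "trial_design"
  )
}

#' Standard stepped wedge design
#'
#' Builds the standard stepped wedge schematic with `S` sequences and
#' `T = S + 1` periods: no sequence is treated in the first period, one
#' sequence crosses from control to intervention at the start of each
#' subsequent period, and all sequences are treated in the final period.
#' Sequence s is treated in periods t > s.
#'
#' @param S Number of treatment sequences (at least 2).
#' @inheritParams trial_design
#' @return A [trial_design()] with `T = S + 1` periods.
#' @examples
#' stepped_wedge(3, clusters_per_sequence = 4, m = 10)
#' @export
stepped_wedge <- function(S, clusters_per_sequence = 1L, m = 1,
                          label = "stepped wedge") {
  if (S < 2) stop("invalid-design: a stepped wedge needs at least 2 sequences",
                  call. = FALSE)
  S <- as.integer(S)
  schematic <- outer(seq_len(S), seq_len(S + 1L), function(s, t) as.integer(t > s))
  trial_design(schematic, clusters_per_sequence, m, label)
}

#' Parallel longitudinal design
#'
#' Two sequences measured over `periods` periods: one always on intervention,
#' one always on control.
#'
#' @param periods Number of measurement periods (at least 2).
#' @inheritParams trial_design
#' @return A [trial_design()].
#' @export
parallel_design <- function(periods, clusters_per_sequence = c(1L, 1L), m = 1,
                            label = "parallel") {
  periods <- as.integer(periods)
  schematic <- rbind(rep(1L, periods), rep(0L, periods))
  trial_design(schematic, clusters_per_sequence, m, label)
}

#' Two-sequence cluster crossover design
#'
#' The classical AB/BA cluster crossover over two periods.
#'
#' @inheritParams trial_design
#' @return A [trial_design()].
#' @export
cluster_crossover <- function(clusters_per_sequence = c(1L, 1L), m = 1,
                              label = "cluster crossover") {
  trial_design(rbind(c(0L, 1L), c(1L, 0L)), clusters_per_sequence, m, label)
}

#' Expand a design to per-cluster treatment vectors
#'
#' Replicates each sequence row of the schematic once per assigned cluster, in
#' sequence-major, stable order, so that every cluster has its own row. All
#' design-effect and GLS computations operate on this expanded matrix.
#'
#' @param design A [trial_design()].
#' @return A K x T integer matrix of treatment indicators with an attribute
#'   `sequence` giving each cluster's sequence index.
#' @export
expand_to_clusters <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  seq_idx <- rep(seq_len(design$S), times = design$clusters_per_sequence)
  Xc <- design$schematic[seq_idx, , drop = FALSE]
  rownames(Xc) <- paste0("cluster_", seq_len(nrow(Xc)))
  attr(Xc, "sequence") <- seq_idx
  Xc
}

#' Treatment totals of an expanded design matrix
#'
#' Computes the grand total of treated cluster-periods, the per-period column
#' totals and the per-cluster row totals of a binary cluster-by-period
#' treatment matrix. These are the summaries the design effect is built from.
#'
#' @param Xc Binary K x T matrix (typically from [expand_to_clusters()]).
#' @return A list with elements `grand` (scalar), `period` (length-T vector)
#'   and `cluster` (length-K vector).
#' @export
design_totals <- function(Xc) {
  Xc <- as.matrix(Xc)
  if (!all(Xc %in% c(0, 1))) {
    stop("invalid-design: treatment matrix entries must be 0 or 1", call. = FALSE)
  }
  list(grand = sum(Xc),
       period = unname(colSums(Xc)),
       cluster = unname(rowSums(Xc)))
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("Longitudinal CRT design%s\n",
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  cat(sprintf("  %d sequence(s) x %d periods, %d cluster(s) in total, m = %d per cluster-period\n",
              x$S, x$T, x$K, x$m))
  sch <- x$schematic
  rownames(sch) <- sprintf("%s (x%d)", rownames(sch), x$clusters_per_sequence)
  print(sch)
  invisible(x)
}
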