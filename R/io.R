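#' Read and write trial design schematics
#'
#' A design is stored as a CSV schematic (one header row `period_1..period_T`,
#' one row per sequence, entries 0/1) plus a sidecar JSON or YAML config
#' carrying `clusters_per_sequence`, `m` and an optional `label`.
#'
#' @param design A [trial_design()].
#' @param csv Path of the schematic CSV.
#' @param config Path of the sidecar config (`.json`, `.yaml` or `.yml`).
#' @return `read_design()` returns a [trial_design()]; `write_design()`
#'   returns the design invisibly.
#' @export
write_design <- function(design, csv, config) {
  stopifnot(inherits(design, "trial_design"))
  utils::write.csv(as.data.frame(design$schematic), csv, row.names = FALSE)
  side <- list(clusters_per_sequence = design$clusters_per_sequence,
               m = design$m, label = design$label)
  if (grepl("\\.ya?ml$", config)) {
    yaml::write_yaml(side, config)
  } else {
    jsonlite::write_json(side, config, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(design)
}

#' @rdname write_design
#' @export
read_design <- function(csv, config) {
  schematic <- as.matrix(utils::read.csv(csv, check.names = FALSE))
  side <- .read_config_file(config)
  trial_design(schematic,
               clusters_per_sequence = unlist(side$clusters_per_sequence),
               m = side$m,
               label = if (is.null(side$label)) "" else side$label)
}

.read_config_file <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Parse a full analysis config
#'
#' Reads a single JSON or YAML configuration describing a design, a
#' correlation model, a sampling scheme and the effect/test parameters, and
#' returns the corresponding package objects. This is the format the
#' command-line interface consumes. Blocks:
#'
#' \preformatted{
#' design:
#'   type: stepped_wedge          # or parallel | crossover | schematic
#'   sequences: 3                 # stepped_wedge
#'   periods: 4                   # parallel
#'   schematic: [[0,1],[1,0]]     # type: schematic
#'   clusters_per_sequence: 4
#'   m: 10
#' correlation:
#'   model: block_exchangeable    # or decay
#'   sigma2: 25
#'   rho: 0.33
#'   pi: 0.9                      # pi_D / tau_D for model: decay
#'   tau: 0.7
#' scheme:
#'   kind: constant_churn         # closed_population | beta_churn | in_for_p | custom
#'   chi: 0
#' effect:
#'   theta: 2
#'   alpha: 0.05
#'   target_power: 0.9
#' }
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with elements `design`, `vc`, `scheme`, `theta`, `alpha`,
#'   `target_power` (the latter `NULL` when absent).
#' @export
read_analysis_config <- function(path) {
  cfg <- .read_config_file(path)
  d <- cfg$design
  design <- switch(
    if (is.null(d$type)) "schematic" else d$type,
    stepped_wedge = stepped_wedge(d$sequences,
                                  .or1(d$clusters_per_sequence), d$m),
    parallel = parallel_design(d$periods, .or1(d$clusters_per_sequence), d$m),
    crossover = cluster_crossover(.or1(d$clusters_per_sequence), d$m),
    schematic = trial_design(do.call(rbind, lapply(d$schematic, unlist)),
                             .or1(d$clusters_per_sequence), d$m),
    stop("unknown design type: ", d$type, call. = FALSE)
  )
  co <- cfg$correlation
  vc <- switch(
    if (is.null(co$model)) "block_exchangeable" else co$model,
    block_exchangeable = variance_components(co$sigma2, co$rho, co$pi, co$tau),
    decay = decay_components(co$sigma2, co$rho,
                             if (is.null(co$pi_D)) co$pi else co$pi_D,
                             if (is.null(co$tau_D)) co$tau else co$tau_D),
    stop("unknown correlation model: ", co$model, call. = FALSE)
  )
  sc <- cfg$scheme
  scheme <- sampling_scheme(
    sc$kind,
    chi = sc$chi, M = sc$M, alpha = sc$alpha, beta = sc$beta, p = sc$p,
    table = if (!is.null(sc$table)) do.call(rbind, lapply(sc$table, unlist))
  )
  ef <- cfg$effect
  list(design = design, vc = vc, scheme = scheme,
       theta = ef$theta,
       alpha = if (is.null(ef$alpha)) 0.05 else ef$alpha,
       target_power = ef$target_power)
}

.or1 <- function(x) if (is.null(x)) 1L else unlist(x)

#' Write a simulated trial dataset to CSV
#'
#' @param dataset Data frame from [simulate_trial()].
#' @param path Output CSV path.
#' @export
write_trial_dataset <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE)
  invisible(dataset)
}

#' Write a membership matrix to CSV
#'
#' @param membership A [membership_matrix()].
#' @param path Output CSV path.
#' @export
write_membership <- function(membership, path) {
  n <- membership$n
  colnames(n) <- paste0("period_", seq_len(ncol(n)))
  utils::write.csv(as.data.frame(n), path, row.names = FALSE)
  invisible(membership)
}
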