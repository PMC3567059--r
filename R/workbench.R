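#' Run a batch of replicate networks and aggregate their measurements
#'
#' Generates `replicates` networks from one model with seeds
#' `seed, seed + 1, ...`, measures each with [measure_graph()], and
#' aggregates per-measurement means and standard deviations together
#' with the pooled degree sequence. Identical `(model, params,
#' replicates, seed)` inputs give identical reports.
#'
#' @param model One of `"sfn"`, `"sen"`, `"er"`, `"ws"`, `"ba"`.
#' @param params Model parameters: an [sfn_params()] / [sen_params()]
#'   object, or a named list (`n`, `p` for er; `n`, `K`, `p` for ws;
#'   `n`, `m` for ba).
#' @param replicates Number of replicates, `>= 1`.
#' @param seed Integer base seed.
#' @return An object of class `"aggregate_report"`: `stats` (data frame
#'   with measure, mean, sd), `pooled_degrees`, `model`, `replicates`,
#'   `seed`.
#' @examples
#' rep <- run_batch("sfn", sfn_params(108, 7, 9.315, 0.2),
#'                  replicates = 5, seed = 1)
#' rep
#' @export
run_batch <- function(model = c("sfn", "sen", "er", "ws", "ba"), params,
                      replicates = 100, seed = 1) {
  model <- match.arg(model)
  replicates <- check_count(replicates, "replicates", min = 1L)
  gen <- switch(model,
    sfn = function(s) generate_sfn(params, seed = s),
    sen = function(s) generate_sen(params, seed = s),
    er = function(s) generate_er(params$n, params$p, seed = s),
    ws = function(s) generate_ws(params$n, params$K, params$p, seed = s),
    ba = function(s) generate_ba(params$n, params$m, seed = s))
  rows <- vector("list", replicates)
  degrees <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    g <- tryCatch(gen(seed + r - 1L), error = function(e)
      stop_bad_arg("replicate with seed ", seed + r - 1L, " failed: ",
                   conditionMessage(e)))
    rows[[r]] <- unlist(unclass(measure_graph(g)))
    degrees[[r]] <- igraph::degree(g)
  }
  mm <- do.call(rbind, rows)
  structure(list(
    stats = data.frame(measure = colnames(mm),
                       mean = apply(mm, 2, mean),
                       sd = if (replicates == 1L) rep(0, ncol(mm))
                            else apply(mm, 2, sd),
                       row.names = NULL, stringsAsFactors = FALSE),
    pooled_degrees = unlist(degrees, use.names = FALSE),
    model = model, params = params, replicates = replicates,
    seed = seed), class = "aggregate_report")
}

#' @export
print.aggregate_report <- function(x, digits = 4, ...) {
  cat(sprintf("Aggregate report: %s model, %d replicates (seed %d)\n",
              toupper(x$model), x$replicates, x$seed))
  labs <- c(order = "Order", size = "Size", mean_degree = "<k>",
            diameter = "Diameter", density = "Density",
            clustering = "Clustering", geodesic = "Geodesic",
            betweenness = "Betweenness", closeness = "Closeness")
  st <- x$stats
  for (nm in names(labs)) {
    i <- match(nm, st$measure)
    cat(sprintf("  %-12s %10s  (sd %s)\n", labs[[nm]],
                format(signif(st$mean[i], digits)),
                format(signif(st$sd[i], 3))))
  }
  invisible(x)
}

#' Batch mean of one measurement
#'
#' @param report An `"aggregate_report"`.
#' @param measure Measurement name, e.g. `"size"` or `"clustering"`.
#' @return The mean over replicates.
#' @export
report_mean <- function(report, measure) {
  stopifnot(inherits(report, "aggregate_report"))
  i <- match(measure, report$stats$measure)
  if (is.na(i)) stop_bad_arg("unknown measure: ", measure)
  report$stats$mean[i]
}

#' Compare a batch's pooled degrees against a reference sample
#'
#' Two-sample Kolmogorov–Smirnov test of the pooled degree sequence of
#' an [run_batch()] report against a reference degree sample (for
#' example the degree sequence observed in a school, or a Poisson
#' sample).
#'
#' @param report An `"aggregate_report"`.
#' @param reference A numeric degree sample, or a
#'   `"degree_distribution"` object (expanded via
#'   [as_degree_sequence()]).
#' @return A list with `D` and `p_value`.
#' @export
compare_to_reference <- function(report, reference) {
  stopifnot(inherits(report, "aggregate_report"))
  if (inherits(reference, "degree_distribution"))
    reference <- as_degree_sequence(reference)
  ks_two_sample(report$pooled_degrees, reference)
}

#' Serialize an aggregate report
#'
#' Writes the per-measurement means and standard deviations as CSV with
#' a fixed row order.
#'
#' @param report An `"aggregate_report"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "aggregate_report"))
  order_ <- c("order", "size", "mean_degree", "diameter", "density",
              "clustering", "geodesic", "betweenness", "closeness")
  st <- report$stats[match(order_, report$stats$measure), ]
  utils::write.csv(st, path, row.names = FALSE)
  invisible(path)
}
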