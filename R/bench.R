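#' Compare the colour and binary pipelines on a phantom suite
#'
#' Runs [segment_lesion()] in both modes on every phantom and scores each
#' result against the exact ground truth: one row per (image, method) with
#' border error, precision and recall, plus a summary counting the images
#' where the colour (normalized-distance) pipeline achieves a strictly
#' lower border error than the binary baseline.
#'
#' @param suite a [make_suite()] result, or a list of items each holding
#'   `image` and `mask`.
#' @param params_nd,params_binary optional [cluster_params()] overrides per
#'   mode (package defaults otherwise).
#' @param config a [lesion_config()].
#' @param verbose print per-image progress.
#' @return A list of class `bench_result`: `table` (data.frame with columns
#'   `image`, `method`, `border_error`, `precision`, `recall`,
#'   `queries_fired`, `queries_skipped`) and `summary` (list with `n`,
#'   `nd_better`, `nd_not_worse`, `mean_be_nd`, `mean_be_binary`,
#'   `median_be_nd`, `median_be_binary`).
#' @export
bench_phantoms <- function(suite, params_nd = NULL, params_binary = NULL,
                           config = lesion_config(), verbose = FALSE) {
  items <- if (inherits(suite, "phantom_suite")) suite$items else suite
  if (!length(items)) {
    warning("empty suite: nothing to benchmark", call. = FALSE)
    return(structure(list(table = data.frame(), summary = list(n = 0L)),
                     class = "bench_result"))
  }
  rows <- list()
  for (i in seq_along(items)) {
    it <- items[[i]]
    if (is.null(it$mask)) {
      warning("item ", i, " has no ground truth; skipped", call. = FALSE)
      next
    }
    for (method in c("nd-fdbld", "fdbld-binary")) {
      mode <- if (method == "nd-fdbld") "nd" else "binary"
      params <- if (mode == "nd") params_nd else params_binary
      res <- suppressWarnings(
        segment_lesion(it$image, params = params, mode = mode,
                       config = config))
      ev <- evaluate_masks(res$mask, it$mask)
      st <- if (!is.null(res$clustering)) res$clustering$stats else
        list(fired = NA_integer_, skipped = NA_integer_)
      rows[[length(rows) + 1L]] <- data.frame(
        image = i, method = method,
        border_error = ev$border_error,
        precision = ev$precision, recall = ev$recall,
        queries_fired = st$fired, queries_skipped = st$skipped)
    }
    if (verbose) message("phantom ", i, "/", length(items), " done")
  }
  tab <- do.call(rbind, rows)
  be_nd <- tab$border_error[tab$method == "nd-fdbld"]
  be_bin <- tab$border_error[tab$method == "fdbld-binary"]
  summary <- list(
    n = length(be_nd),
    nd_better = sum(be_nd < be_bin),
    nd_not_worse = sum(be_nd <= be_bin),
    mean_be_nd = mean(be_nd), mean_be_binary = mean(be_bin),
    median_be_nd = stats::median(be_nd),
    median_be_binary = stats::median(be_bin))
  structure(list(table = tab, summary = summary), class = "bench_result")
}

#' @export
print.bench_result <- function(x, ...) {
  s <- x$summary
  if (!s$n) { cat("<bench_result: empty>\n"); return(invisible(x)) }
  cat(sprintf(
    paste0("<bench_result: %d image(s); colour pipeline better on %d;\n",
           "  mean BE %% nd=%.2f binary=%.2f; median BE %% nd=%.2f binary=%.2f>\n"),
    s$n, s$nd_better, s$mean_be_nd, s$mean_be_binary,
    s$median_be_nd, s$median_be_binary))
  invisible(x)
}

#' Write a bench result to CSV and JSON
#'
#' @param bench a [bench_phantoms()] result.
#' @param csv,json output paths (either may be `NULL` to skip).
#' @return `bench`, invisibly.
#' @export
write_bench <- function(bench, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(bench$table, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(table = bench$table, summary = bench$summary),
                         json, auto_unbox = TRUE, digits = NA)
  invisible(bench)
}
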