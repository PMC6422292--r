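#' Run the (full or filtered) configuration sweep
#'
#' Simulates every enumerated configuration in deterministic (RT, SS, PI,
#' SVA) order and binds the per-configuration load results.  Any
#' configuration failure aborts with the offending parameter tuple in the
#' error message.
#'
#' @param constants Model constants.
#' @param rt,ss_range,pi_range,sva Optional grid filters, see
#'   [enumerate_sweep()].
#' @param progress Print a progress line every 250 configurations.
#' @return A data.frame (`sweep_result`) with one [simulate_configuration()]
#'   row per configuration; the full grid has 2772 rows.
#' @export
run_sweep <- function(constants = default_constants(), rt = NULL,
                      ss_range = NULL, pi_range = NULL, sva = NULL,
                      progress = FALSE) {
  grid <- enumerate_sweep(constants, rt = rt, ss_range = ss_range,
                          pi_range = pi_range, sva = sva)
  n <- nrow(grid)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- tryCatch(
      simulate_configuration(grid[i, ], constants),
      error = function(e) {
        stop(sprintf("configuration (%s, SS %g, PI %g, SVA %s) failed: %s",
                     grid$rt[i], grid$ss[i], grid$pi[i],
                     grid$sva_condition[i], conditionMessage(e)),
             call. = FALSE)
      })
    if (progress && i %% 250 == 0) {
      message(sprintf("  %d / %d configurations", i, n))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Aggregate a sweep into median-and-range cells
#'
#' For each output quantity, lumbar type and SVA condition, computes the
#' median and the min-max range over the SS x PI grid (the layout of the
#' descriptive tables: forces are arranged as near-planar surfaces over the
#' grid, so median and range are the appropriate summaries).  The median of
#' an even-count cell is the midpoint of the two central order statistics.
#'
#' @param sweep A `sweep_result` data.frame.
#' @param outputs Character vector of output columns to aggregate.
#' @return A data.frame with columns `output`, `rt`, `sva_condition`,
#'   `median`, `min`, `max`, `n`.
#' @export
aggregate_sweep <- function(sweep,
                            outputs = c("fl4l5c", "fl4l5s", "fl5s1c",
                                        "fl5s1s", "f_mf", "f_es", "f_ra",
                                        "ll_deg")) {
  stopifnot(nrow(sweep) > 0, all(outputs %in% names(sweep)))
  rts <- intersect(rt_labels(), unique(sweep$rt))
  svas <- intersect(sva_conditions(), unique(sweep$sva_condition))
  cells <- expand.grid(output = outputs, rt = rts, sva_condition = svas,
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(k) {
    sel <- sweep$rt == cells$rt[k] & sweep$sva_condition == cells$sva_condition[k]
    v <- sweep[[cells$output[k]]][sel]
    if (length(v) == 0) {
      data.frame(cells[k, ], median = NA_real_, min = NA_real_,
                 max = NA_real_, n = 0L)
    } else {
      data.frame(cells[k, ], median = stats::median(v), min = min(v),
                 max = max(v), n = length(v))
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write a sweep (or aggregate) table as CSV
#'
#' Plain RFC-4180 CSV, one row per configuration or per aggregation cell.
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
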