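#' Experimentally measured contributions to protein-level variance
#'
#' Reference contribution-to-variance fractions for the four reaction
#' processes, from regression-corrected measurements of mammalian
#' housekeeping-gene mRNA and protein abundances (Li et al. 2014, via the
#' "measured protein error" re-analysis of the Schwanhausser et al. 2011
#' data set): transcription 0.38, mRNA decay 0.18, translation 0.30, protein
#' decay 0.14. Diffusion has no experimental counterpart in cultured cells;
#' for six-way comparisons both diffusion entries are treated as 0.
#'
#' @param mode `"six_way"` (default) returns all six parameters with the
#'   diffusion entries set to 0; `"four_way"` returns only the four
#'   reaction parameters.
#' @return A named numeric vector of contribution fractions.
#' @export
reference_contributions <- function(mode = c("six_way", "four_way")) {
  mode <- match.arg(mode)
  ref <- c(sigma = 0.38, d = 0, lam = 0.18, tau = 0.30, delta = 0,
           gamma = 0.14)
  if (mode == "four_way") ref <- ref[c("sigma", "lam", "tau", "gamma")]
  ref
}

#' Compare first-order sensitivities with the measured contributions
#'
#' Pairs computed first-order sensitivity indices with the experimental
#' contribution-to-variance reference and reports the Pearson correlation and
#' the maximum absolute difference over the compared pairs. In `"six_way"`
#' mode (default) the diffusion parameters are paired with reference 0 --
#' the reading under which the model-vs-experiment agreement statistics are
#' defined; `"four_way"` restricts to the four reaction parameters.
#'
#' @param first_order named numeric vector of first-order indices covering
#'   all six parameters (e.g. `hdmr_result$first_order`).
#' @param mode `"six_way"` or `"four_way"`.
#' @return A list with `pearson_r` and `max_abs_diff`.
#' @export
compare_to_reference <- function(first_order, mode = c("six_way", "four_way")) {
  mode <- match.arg(mode)
  ref <- reference_contributions(mode)
  missing <- setdiff(names(ref), names(first_order))
  if (length(missing) > 0L) {
    stop("'first_order' is missing parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  s <- first_order[names(ref)]
  list(pearson_r = stats::cor(s, ref),
       max_abs_diff = max(abs(s - ref)))
}

#' The default analysis grid
#'
#' Enumerates the full factorial analysis grid: five initial conditions
#' (ubiquitous at levels 0, 1/2 and 1; anterior and posterior maternal
#' deposits), four spatial objectives (anterior, middle and posterior
#' nucleus, and the spatial mean) and eleven evenly spaced analysis times
#' spanning the twenty-minute window (0, 2, ..., 20 min) -- 220 cells.
#'
#' @param times analysis time points in minutes.
#' @return A data frame with columns `ic`, `level`, `spatial`, `time` and a
#'   `key` string `"<ic>/<spatial>/t<time>"`.
#' @export
default_analysis_grid <- function(times = seq(0, 20, by = 2)) {
  ics <- data.frame(
    ic = c("ubiquitous_0", "ubiquitous_05", "ubiquitous_1", "anterior",
           "posterior"),
    kind = c("ubiquitous", "ubiquitous", "ubiquitous", "anterior",
             "posterior"),
    level = c(0, 0.5, 1, 1, 1))
  g <- expand.grid(i = seq_len(nrow(ics)), spatial = .spatial_kinds,
                   time = times, stringsAsFactors = FALSE)
  out <- data.frame(ic = ics$ic[g$i], kind = ics$kind[g$i],
                    level = ics$level[g$i], spatial = g$spatial,
                    time = g$time, stringsAsFactors = FALSE)
  out$key <- sprintf("%s/%s/t%g", out$ic, out$spatial, out$time)
  out
}

#' Run the HDMR sensitivity analysis over the full grid
#'
#' For each initial condition the model is integrated once for all design
#' points (all analysis times recorded from the same trajectories), then an
#' HDMR decomposition is computed per (spatial objective, time) cell. Cells
#' at `t = 0` use the zero-variance convention -- every parameter set
#' returns the initial condition, so all indices are zero -- without running
#' any simulation. Results can be cached to disk per initial condition so
#' interrupted grids resume cheaply.
#'
#' @param space a [parameter_space()].
#' @param n_samples Sobol design size per HDMR run (default 8192).
#' @param grid a data frame as returned by [default_analysis_grid()].
#' @param degree polynomial degree for [hdmr_decompose()].
#' @param dt integration step in minutes.
#' @param n_nuclei number of nuclei.
#' @param cache_dir optional directory for per-initial-condition caches.
#' @param verbose print per-cell progress.
#' @return A named list of `hdmr_result` objects keyed by `grid$key`, with
#'   the grid attached as attribute `"grid"`.
#' @export
run_sensitivity_grid <- function(space = default_parameter_space(),
                                 n_samples = 8192L,
                                 grid = default_analysis_grid(),
                                 degree = 3L, dt = 0.01, n_nuclei = 52L,
                                 cache_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(space, "parameter_space"),
            all(c("ic", "kind", "level", "spatial", "time", "key") %in%
                  names(grid)))
  design <- sobol_design(n_samples, space)
  results <- vector("list", nrow(grid))
  names(results) <- grid$key
  for (ic_name in unique(grid$ic)) {
    rows <- grid[grid$ic == ic_name, ]
    cache_file <- if (!is.null(cache_dir)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      file.path(cache_dir, paste0("grid_", ic_name, "_N", n_samples, ".rds"))
    }
    if (!is.null(cache_file) && file.exists(cache_file)) {
      cached <- readRDS(cache_file)
      results[rows$key] <- cached[rows$key]
      next
    }
    ic <- initial_condition(rows$kind[1L], rows$level[1L], n_nuclei)
    nonzero_times <- sort(unique(rows$time[rows$time > 0]))
    ic_results <- list()
    for (spatial in unique(rows$spatial)) {
      outputs <- if (length(nonzero_times) > 0L) {
        evaluate_objective_batch(design, ic, spatial, times = nonzero_times,
                                 dt = dt, n_nuclei = n_nuclei)
      }
      for (time in unique(rows$time)) {
        key <- rows$key[rows$spatial == spatial & rows$time == time]
        h <- if (time == 0) {
          hdmr_decompose(design, rep(extract_ic_objective(ic, spatial,
                                                          n_nuclei),
                                     n_samples), degree = degree)
        } else {
          hdmr_decompose(design, outputs[, paste0("t", time)],
                         degree = degree)
        }
        ic_results[[key]] <- h
        if (verbose) message("done: ", key)
      }
    }
    if (!is.null(cache_file)) saveRDS(ic_results, cache_file)
    results[names(ic_results)] <- ic_results
  }
  attr(results, "grid") <- grid
  results
}

# objective value implied by an initial condition (t = 0 cells)
extract_ic_objective <- function(ic, spatial, n_nuclei) {
  prot <- as.numeric(ic)[n_nuclei + seq_len(n_nuclei)]
  if (spatial == "spatial_mean") return(mean(prot))
  prot[.spatial_index(spatial, n_nuclei)]
}

#' Per-parameter sensitivity trajectories over the analysis window
#'
#' Reshapes grid results for one initial condition and one spatial objective
#' into a parameters-by-times matrix of first-order indices. By the
#' zero-variance convention the `t = 0` column is exactly zero for every
#' parameter.
#'
#' @param results a list from [run_sensitivity_grid()] (grid attached).
#' @param ic initial-condition label, e.g. `"ubiquitous_1"`.
#' @param spatial spatial objective label, e.g. `"middle_nucleus"`.
#' @return A matrix of class `sensitivity_time_series` (6 rows, one column
#'   per analysis time, named `t<time>`) with attributes `ic` and `spatial`.
#'   Convert with `as.data.frame()` for a figure-ready table.
#' @export
sensitivity_time_series <- function(results, ic, spatial) {
  grid <- attr(results, "grid")
  if (is.null(grid)) stop("'results' must carry its analysis grid",
                          call. = FALSE)
  rows <- grid[grid$ic == ic & grid$spatial == spatial, ]
  if (nrow(rows) == 0L) {
    stop("no grid cells for ic = ", ic, ", spatial = ", spatial,
         call. = FALSE)
  }
  rows <- rows[order(rows$time), ]
  missing <- rows$key[!rows$key %in% names(results) |
                        vapply(results[rows$key], is.null, logical(1L))]
  if (length(missing) > 0L) {
    stop("missing grid cell(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  series <- vapply(rows$key, function(k) results[[k]]$first_order,
                   numeric(6L))
  colnames(series) <- paste0("t", rows$time)
  structure(series, class = c("sensitivity_time_series", "matrix"),
            ic = ic, spatial = spatial, times = rows$time)
}

#' @export
as.data.frame.sensitivity_time_series <- function(x, ...) {
  data.frame(parameter = rownames(x), unclass(x), check.names = FALSE,
             row.names = NULL)
}

#' @export
print.sensitivity_time_series <- function(x, digits = 3, ...) {
  cat(sprintf("First-order sensitivities over time (%s, %s):\n",
              attr(x, "ic"), attr(x, "spatial")))
  print(round(unclass(x), digits))
  invisible(x)
}
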