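#' Specify an accuracy-vs-group-size experiment
#'
#' Bundles a decision ecology, a quorum fraction, a grid of group sizes and
#' the computation method into one reproducible experiment description.
#' The default group-size grid uses odd sizes 1, 3, ..., 501 so that a
#' simple-majority quorum never ties.
#'
#' @param ecology A [decision_ecology()].
#' @param q Quorum fraction.
#' @param n_values Strictly increasing group sizes, all >= 1.
#' @param method `"exact"`, `"sim"`, or `"both"`.
#' @param n_reps Replicates per simulated point.
#' @param seed Base seed; simulated points at successive group sizes use
#'   `seed`, `seed + 1`, ... so each point is independently reproducible.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(ecology, q, n_values = seq(1L, 501L, by = 2L),
                            method = c("exact", "sim", "both"),
                            n_reps = 10000L, seed = 1L) {
  stopifnot(inherits(ecology, "decision_ecology"),
            is.numeric(q), length(q) == 1L, q >= 0, q < 1,
            is.numeric(n_values), length(n_values) >= 1,
            all(n_values >= 1), all(n_values == round(n_values)),
            all(diff(n_values) > 0))
  method <- match.arg(method)
  structure(list(ecology = ecology, q = q,
                 n_values = as.integer(n_values), method = method,
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "experiment_spec")
}

#' Reference experiment parameter sets
#'
#' The six published illustrative scenarios, labelled `"a"`–`"f"`. All
#' share the cue model `mu_minus = 0`, `mu_plus = sigma = 1` and costs
#' `c_tp = c_tn = 0`, `c_fn = 1`, and differ in false positive cost, prior
#' and quorum:
#'
#' | panel | c_fp | p   | q     | illustrates                    |
#' |-------|------|-----|-------|--------------------------------|
#' | a     | 4    | 0.9 | 0.5   | Error Ia under majority        |
#' | b     | 4    | 0.9 | 0.7   | super-majority remediation     |
#' | c     | 1    | 0.7 | 0.5   | Error Ib under majority        |
#' | d     | 1    | 0.7 | 0.75  | super-majority remediation     |
#' | e     | 10   | 0.7 | 0.5   | Error II under majority        |
#' | f     | 10   | 0.7 | 0.035 | sub-majority remediation       |
#'
#' @param panel One of `"a"`–`"f"`.
#' @param n_values,method,n_reps,seed Passed to [experiment_spec()].
#' @return An `experiment_spec` for the panel.
#' @examples
#' spec <- figure3_panel("a", method = "exact")
#' accuracy_curve(spec)[c(1, 251), ]
#' @export
figure3_panel <- function(panel = c("a", "b", "c", "d", "e", "f"),
                          n_values = seq(1L, 501L, by = 2L),
                          method = c("both", "exact", "sim"),
                          n_reps = 10000L, seed = 1L) {
  panel <- match.arg(panel)
  method <- match.arg(method)
  pars <- switch(panel,
    a = list(c_fp = 4, p = 0.9, q = 0.5),
    b = list(c_fp = 4, p = 0.9, q = 0.7),
    c = list(c_fp = 1, p = 0.7, q = 0.5),
    d = list(c_fp = 1, p = 0.7, q = 0.75),
    e = list(c_fp = 10, p = 0.7, q = 0.5),
    f = list(c_fp = 10, p = 0.7, q = 0.035)
  )
  eco <- decision_ecology(mu_minus = 0, mu_plus = 1, sigma = 1,
                          p = pars$p, c_tp = 0, c_tn = 0,
                          c_fp = pars$c_fp, c_fn = 1)
  experiment_spec(eco, q = pars$q, n_values = n_values, method = method,
                  n_reps = n_reps, seed = seed)
}

#' Group accuracy as a function of group size
#'
#' Runs one experiment: the signal-detection-optimal operating point of the
#' ecology is computed once, then group accuracy is evaluated at every
#' group size — exactly, by simulation, or both. Reference quantities
#' (expected individual accuracy and the large-group limit) are attached as
#' constant columns so any plotting layer can draw them.
#'
#' @param spec An [experiment_spec()].
#' @return A data.frame with one row per group size: columns `n`, `q`,
#'   `accuracy`, `acc_plus`, `acc_minus` (exact, when requested),
#'   `sim_accuracy`, `sim_acc_plus`, `sim_acc_minus`, `std_error`, `seed`
#'   (simulated, when requested), and reference columns `ref_individual`
#'   and `ref_limit`.
#' @export
accuracy_curve <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  point <- optimal_operating_point(spec$ecology)
  p <- spec$ecology$p
  out <- data.frame(n = spec$n_values, q = spec$q)

  if (spec$method %in% c("exact", "both")) {
    ex <- lapply(spec$n_values, function(n) {
      group_accuracy_exact(point, p, group_rule(n, spec$q))
    })
    out$accuracy <- vapply(ex, `[[`, numeric(1), "accuracy")
    out$acc_plus <- vapply(ex, `[[`, numeric(1), "acc_plus")
    out$acc_minus <- vapply(ex, `[[`, numeric(1), "acc_minus")
  }
  if (spec$method %in% c("sim", "both")) {
    sims <- lapply(seq_along(spec$n_values), function(i) {
      group_accuracy_sim(point, p, group_rule(spec$n_values[i], spec$q),
                         n_reps = spec$n_reps, seed = spec$seed + i - 1L)
    })
    out$sim_accuracy <- vapply(sims, `[[`, numeric(1), "accuracy")
    out$sim_acc_plus <- vapply(sims, `[[`, numeric(1), "acc_plus")
    out$sim_acc_minus <- vapply(sims, `[[`, numeric(1), "acc_minus")
    out$std_error <- vapply(sims, `[[`, numeric(1), "std_error")
    out$seed <- vapply(sims, function(s) as.numeric(s$seed), numeric(1))
  }
  out$ref_individual <- expected_accuracy(p, point)
  out$ref_limit <- as.numeric(asymptotic_group_accuracy(point, p, spec$q))
  attr(out, "point") <- point
  out
}

#' Export the four error-region maps
#'
#' Computes the `ia`, `ib`, `ii` and `any` maps for the reference cue model
#' (`mu_minus = 0`, `mu_plus = sigma = 1`, unit false-negative cost, cost
#' ratio on the y axis) and writes each as a long-format CSV
#' (`p,ratio,a_plus,a_minus,error_class`), plus a JSON metadata sidecar
#' recording the grids, the ecology template and a timestamp.
#'
#' @param out_dir Destination directory (created if missing).
#' @param p_grid,ratio_grid Grid definitions, as in [region_map()].
#' @param template Shared ecology parameters, as in [region_map()].
#' @return Invisibly, a named list of the four `error_region_map` objects;
#'   files `map_ia.csv`, `map_ib.csv`, `map_ii.csv`, `map_any.csv` and
#'   `maps_metadata.json` are written to `out_dir`.
#' @export
figure2_maps <- function(out_dir,
                         p_grid = seq(0.005, 0.995, length.out = 201),
                         ratio_grid = 10^seq(-2, 2, length.out = 201),
                         template = list(mu_minus = 0, mu_plus = 1,
                                         sigma = 1)) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  kinds <- c("ia", "ib", "ii", "any")
  maps <- lapply(kinds, function(w) {
    region_map(template = template, p_grid = p_grid,
               ratio_grid = ratio_grid, which = w)
  })
  names(maps) <- kinds
  for (w in kinds) {
    write_region_map(maps[[w]], file.path(out_dir, paste0("map_", w, ".csv")))
  }
  meta <- list(
    p_grid = list(min = min(p_grid), max = max(p_grid),
                  steps = length(p_grid), scale = "linear"),
    ratio_grid = list(min = min(ratio_grid), max = max(ratio_grid),
                      steps = length(ratio_grid), scale = "log"),
    template = maps[["any"]]$template,
    version = as.character(utils::packageVersion("quorumsdt")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(meta, file.path(out_dir, "maps_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(maps)
}
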