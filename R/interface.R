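# Experiment driver and file output. The regime report reproduces the
# figure-level experiments of the model in one table: for each kappa it runs
# the moving-boundary solver, classifies the large-time regime, and compares
# the measured front speed / stationary front position against the
# travelling-wave shooting method and the small-|kappa| asymptotic laws.

#' Run the regime-report experiment over a sweep of kappa
#'
#' For each value of `kappa`, integrates the moving-boundary model from the
#' given initial condition, classifies the large-time regime of the tissue
#' edge, and attaches the relevant comparator: the shooting wave speed for
#' `kappa > 0` (with the relative PDE/shooting discrepancy), or the
#' asymptotic stationary front position for `kappa < 0` with `|kappa| << 1`.
#' Failures in a single row are caught and recorded; the sweep continues.
#'
#' @param kappas numeric vector of net growth parameters.
#' @param s,mu,eta remaining dimensionless parameters (defaults 0.2, 1, 1).
#' @param ic an [initial_condition()]; default the standard quadratic
#'   seeding profile (`omega = 0.03`, `L0 = 1`).
#' @param ap an [alpha_beta()] object for the small-|kappa| comparators;
#'   default from `A0 = 0.05, B0 = 0.01` (only used when `|kappa| <= 0.05`
#'   and the run started from the matching cosh profile).
#' @param n_grid,t_end solver controls; `t_end = NA` picks
#'   `max(50, 10/|kappa|)` per row (50 when `kappa = 0`).
#' @return Data frame with one row per kappa: `kappa`, `regime`, `L_end`,
#'   `dLdt_end`, `c_pde`, `c_shooting`, `c_rel_err`, `L_inf_pred`,
#'   `L_inf_rel_err`, `note`.
#' @export
#' @examples
#' \donttest{
#' regime_report(c(0.3, 0, -0.3), n_grid = 51)
#' }
regime_report <- function(kappas, s = 0.2, mu = 1, eta = 1,
                          ic = make_ic_quadratic(0.03, 1, s),
                          ap = alpha_beta(0.05, 0.01),
                          n_grid = 101L, t_end = NA) {
  rows <- lapply(kappas, function(k) {
    row <- data.frame(kappa = k, regime = NA_character_, L_end = NA_real_,
                      dLdt_end = NA_real_, c_pde = NA_real_,
                      c_shooting = NA_real_, c_rel_err = NA_real_,
                      L_inf_pred = NA_real_, L_inf_rel_err = NA_real_,
                      note = "", stringsAsFactors = FALSE)
    tryCatch({
      te <- if (is.na(t_end)) if (k == 0) 50 else max(50, 10 / abs(k)) else t_end
      q <- nondim_params(kappa = k, s = s, mu = mu, eta = eta)
      st <- solver_settings(n_grid = n_grid, t_end = te)
      tr <- solve_moving_boundary(q, ic, st)
      cls <- suppressWarnings(classify_regime(q, tr))
      row$regime <- cls$label
      row$L_end <- tr$L_values[length(tr$times)]
      row$dLdt_end <- cls$dLdt_end
      if (k > 0) {
        fs <- suppressWarnings(front_speed(tr, c(0.7 * te, te)))
        ws <- wave_speed_shooting(q)
        row$c_pde <- fs$speed
        row$c_shooting <- ws$c
        row$c_rel_err <- abs(fs$speed - ws$c) / ws$c
      }
      if (k < 0 && abs(k) <= 0.05 && identical(ic$descriptor, "cosh")) {
        row$L_inf_pred <- L_infinity(k, ap$alpha)
        row$L_inf_rel_err <- abs(row$L_end - row$L_inf_pred) / row$L_inf_pred
      }
      row
    }, error = function(e) { row$note <- conditionMessage(e); row })
  })
  do.call(rbind, rows)
}

#' Write a computation result to disk with a reproducibility manifest
#'
#' Writes CSV data files plus a JSON manifest holding every resolved
#' parameter and setting, into a fresh timestamped subdirectory of `dir`
#' (distinct runs never overwrite). Numbers are written at full double
#' precision, so re-running from the manifest reproduces the CSVs
#' byte-for-byte on the same platform.
#'
#' For a `"trajectory"`: `edge.csv` (t, L, dLdt), `profiles.csv` (one row
#' per report time, header row of xi values) and `manifest.json`. For a
#' `"wave_speed_result"`: `profile.csv` (z, n, q) and `manifest.json`. For a
#' regime-report data frame: `report.csv` and `manifest.json`.
#'
#' @param x a `"trajectory"`, `"wave_speed_result"`, or regime-report data
#'   frame.
#' @param dir output directory (created if needed).
#' @param label optional label used in the subdirectory name.
#' @return Invisibly, the manifest as a list (field `path` gives the run
#'   directory).
#' @export
write_outputs <- function(x, dir, label = NULL) {
  stamp <- format(Sys.time(), "%Y%m%d-%H%M%OS3")
  sub <- paste0(stamp, if (!is.null(label)) paste0("-", label))
  run_dir <- file.path(dir, sub)
  i <- 0L
  while (dir.exists(run_dir)) {           # same-millisecond collision guard
    i <- i + 1L
    run_dir <- file.path(dir, paste0(sub, "-", i))
  }
  dir.create(run_dir, recursive = TRUE)
  fmt <- function(v) formatC(v, format = "g", digits = 17)

  if (inherits(x, "trajectory")) {
    edge <- data.frame(t = fmt(x$times), L = fmt(x$L_values),
                       dLdt = fmt(x$dLdt_values))
    utils::write.csv(edge, file.path(run_dir, "edge.csv"), row.names = FALSE,
                     quote = FALSE)
    prof <- as.data.frame(apply(x$n_values, 2, fmt))
    names(prof) <- fmt(x$xi)
    utils::write.csv(cbind(t = fmt(x$times), prof),
                     file.path(run_dir, "profiles.csv"),
                     row.names = FALSE, quote = FALSE)
    manifest <- list(kind = "trajectory", path = run_dir,
                     params = unclass(x$params),
                     settings = unclass(x$settings),
                     ic_descriptor = x$ic_descriptor,
                     transformed = x$transformed,
                     files = c("edge.csv", "profiles.csv"))
  } else if (inherits(x, "wave_speed_result")) {
    prof <- wave_profile(x)
    utils::write.csv(data.frame(z = fmt(prof$z), n = fmt(prof$n),
                                q = fmt(prof$q)),
                     file.path(run_dir, "profile.csv"),
                     row.names = FALSE, quote = FALSE)
    manifest <- list(kind = "wave_speed_result", path = run_dir,
                     params = unclass(x$problem$params),
                     epsilon = x$problem$epsilon,
                     n_floor = x$problem$n_floor,
                     c = x$c, mismatch = x$mismatch,
                     iterations = x$iterations,
                     files = "profile.csv")
  } else if (is.data.frame(x)) {
    utils::write.csv(x, file.path(run_dir, "report.csv"), row.names = FALSE)
    manifest <- list(kind = "regime_report", path = run_dir,
                     files = "report.csv")
  } else stop("don't know how to write an object of class ",
              paste(class(x), collapse = "/"), call. = FALSE)

  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a trajectory written by [write_outputs()]
#'
#' Round-trips the CSV + manifest representation back into a
#' `"trajectory"`-shaped list (profile matrix, edge history, parameters).
#'
#' @param run_dir a run directory created by [write_outputs()].
#' @return A list with fields `xi`, `times`, `n_values`, `L_values`,
#'   `dLdt_values`, `params` (plain list), `manifest`.
#' @export
read_trajectory <- function(run_dir) {
  manifest <- jsonlite::read_json(file.path(run_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$kind, "trajectory"))
    stop("run directory does not hold a trajectory", call. = FALSE)
  edge <- utils::read.csv(file.path(run_dir, "edge.csv"))
  prof <- utils::read.csv(file.path(run_dir, "profiles.csv"),
                          check.names = FALSE)
  xi <- as.numeric(names(prof)[-1])
  list(xi = xi, times = edge$t,
       n_values = unname(as.matrix(prof[, -1, drop = FALSE])),
       L_values = edge$L, dLdt_values = edge$dLdt,
       params = manifest$params, manifest = manifest)
}
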