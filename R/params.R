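#' Algorithm parameters for SDR curve computation
#'
#' Container for the tuning parameters of the three-path detection algorithm.
#' The defaults are the published operating point of the method:
#' `n_stack = 150` images per analysis window, `n_select = 15` images per
#' random-subset median, `n_rep = 100` repetitions, superficial row band
#' rows `r_upper = 1` to `r_lower = 19` (about 4% of the 500-pixel resized
#' depth), polynomial baseline orders 6 for both the narrow-streak and
#' broad-streak paths, detection thresholds `t_green = 2`, `t_red = 5`,
#' `t_blue = 10` gray levels, endpoint inclusion zone `p_include = 25` percent
#' and exclusion zone `p_exclude = 2` percent of columns at each end.
#'
#' @param n_stack Number of images per analysis window.
#' @param n_select Images drawn (without replacement) for each random-subset
#'   median image on the narrow-streak ("green") path.
#' @param n_rep Number of random-subset repetitions on the green path.
#' @param r_upper,r_lower First and last row (1-based, inclusive) of the
#'   superficial band used for the column-wise mean.
#' @param o_poly_green,o_poly_red Orders of the polynomial baseline fits on
#'   the green and red paths.
#' @param t_green,t_red,t_blue Detection thresholds in gray-level units for
#'   the green, red (broad-streak) and blue (endpoint) paths.
#' @param p_include Percent of columns at each end of the curve eligible for
#'   the endpoint (blue) path.
#' @param p_exclude Percent of columns zeroed at each end of the final SDR
#'   curve, suppressing border streaks seen even for healthy transducers.
#' @param seed Integer seed driving the green path's random subset sampling.
#' @return An object of class `sdr_params`.
#' @seealso [compute_sdr_curve()], [read_params()]
#' @export
sdr_params <- function(n_stack = 150L, n_select = 15L, n_rep = 100L,
                       r_upper = 1L, r_lower = 19L,
                       o_poly_green = 6L, o_poly_red = 6L,
                       t_green = 2, t_red = 5, t_blue = 10,
                       p_include = 25, p_exclude = 2,
                       seed = 1L) {
  p <- list(
    n_stack = as.integer(n_stack), n_select = as.integer(n_select),
    n_rep = as.integer(n_rep),
    r_upper = as.integer(r_upper), r_lower = as.integer(r_lower),
    o_poly_green = as.integer(o_poly_green), o_poly_red = as.integer(o_poly_red),
    t_green = as.numeric(t_green), t_red = as.numeric(t_red),
    t_blue = as.numeric(t_blue),
    p_include = as.numeric(p_include), p_exclude = as.numeric(p_exclude),
    seed = as.integer(seed)
  )
  validate_sdr_params(p)
  structure(p, class = "sdr_params")
}

validate_sdr_params <- function(p) {
  stopifnot(
    p$n_stack >= 1, p$n_select >= 1, p$n_select <= p$n_stack, p$n_rep >= 1,
    p$r_upper >= 1, p$r_upper <= p$r_lower,
    p$o_poly_green >= 0, p$o_poly_red >= 0,
    p$t_green > 0, p$t_red > 0, p$t_blue > 0,
    p$p_exclude >= 0, p$p_exclude <= p$p_include, p$p_include <= 50
  )
  invisible(p)
}

#' @export
print.sdr_params <- function(x, ...) {
  cat("SDR algorithm parameters\n")
  cat(sprintf("  stack: n_stack=%d  n_select=%d  n_rep=%d  seed=%d\n",
              x$n_stack, x$n_select, x$n_rep, x$seed))
  cat(sprintf("  band:  rows %d-%d\n", x$r_upper, x$r_lower))
  cat(sprintf("  fits:  order %d (narrow) / %d (broad)\n",
              x$o_poly_green, x$o_poly_red))
  cat(sprintf("  thresholds: green=%g red=%g blue=%g gray levels\n",
              x$t_green, x$t_red, x$t_blue))
  cat(sprintf("  endpoints: include %g%%, exclude %g%%\n",
              x$p_include, x$p_exclude))
  invisible(x)
}

#' Read or write algorithm parameters as a YAML configuration file
#'
#' Keys missing from the file fall back to the defaults of [sdr_params()],
#' so a configuration file only needs to state deviations from the published
#' operating point.
#'
#' @param path Path to a YAML file.
#' @return For `read_params()`, an `sdr_params` object; for `write_params()`,
#'   `path` invisibly.
#' @export
read_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(sdr_params))
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) {
    warning("ignoring unknown parameter keys: ", paste(extra, collapse = ", "))
  }
  do.call(sdr_params, cfg[intersect(names(cfg), known)])
}

#' @rdname read_params
#' @param params An `sdr_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "sdr_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
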