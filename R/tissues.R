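# Dispersive tissue electrical properties over the stimulation band.
#
# Conductivity and relative permittivity are tabulated per tissue at a small
# set of frequencies covering [50, 7500] Hz and interpolated log-linearly in
# frequency. The shipped values are representative low-frequency literature
# values; they are fully overridable from a CSV table, since the exact
# database values used clinically are licence-bound.

#' Tissue electrical properties
#'
#' @param name Tissue name.
#' @param f_hz Tabulated frequencies (Hz), covering at least [50, 7500] Hz.
#' @param sigma_S_per_m Conductivity at each frequency (S/m, >= 0).
#' @param eps_r Relative permittivity at each frequency (> 0).
#' @return Object of class `tissue_properties` with interpolators
#'   `$sigma(f)` and `$eps_r(f)` (log-linear in log-frequency).
#' @export
tissue_properties <- function(name, f_hz, sigma_S_per_m, eps_r) {
  if (any(sigma_S_per_m < 0)) stopf("conductivity must be non-negative (%s)", name)
  if (any(eps_r <= 0)) stopf("relative permittivity must be positive (%s)", name)
  if (min(f_hz) > 50 || max(f_hz) < 7500)
    stopf("property table for %s must cover [50, 7500] Hz", name)
  o <- order(f_hz)
  f_hz <- f_hz[o]; sigma_S_per_m <- sigma_S_per_m[o]; eps_r <- eps_r[o]
  lf <- log(f_hz)
  sig_fun <- function(f) {
    s <- stats::approx(lf, log(pmax(sigma_S_per_m, 1e-300)), xout = log(f),
                       rule = 2)$y
    exp(s)
  }
  eps_fun <- function(f) {
    exp(stats::approx(lf, log(eps_r), xout = log(f), rule = 2)$y)
  }
  structure(list(name = name, f_hz = f_hz, sigma_S_per_m = sigma_S_per_m,
                 eps_r_tab = eps_r, sigma = sig_fun, eps_r = eps_fun),
            class = "tissue_properties")
}

#' @export
print.tissue_properties <- function(x, ...) {
  cat(sprintf("Tissue '%s': sigma %.3g-%.3g S/m, eps_r %.3g-%.3g over [%g, %g] Hz\n",
              x$name, min(x$sigma_S_per_m), max(x$sigma_S_per_m),
              min(x$eps_r_tab), max(x$eps_r_tab), min(x$f_hz), max(x$f_hz)))
  invisible(x)
}

#' Complex conductivity sigma* = sigma + j omega eps0 eps_r
#'
#' @param props A [tissue_properties()].
#' @param f_hz Frequency (Hz); vectorised.
#' @return Complex conductivity in S/m.
#' @export
complex_conductivity <- function(props, f_hz) {
  props$sigma(f_hz) + 2i * pi * f_hz * EPS0 * props$eps_r(f_hz)
}

#' Built-in head tissue property table
#'
#' Returns the default label -> tissue map used by [build_layered_head()]:
#' labels 1..5 are skin, skull (cortical bone), cerebrospinal fluid, grey
#' matter and white matter; label 6 is ischemic edema. Values are tabulated
#' at 8 log-spaced frequencies in [50, 7500] Hz; conductivities are
#' low-frequency literature values and permittivities follow the strong
#' low-frequency dispersion of excitable tissue. Override any entry via
#' [read_tissue_table()].
#'
#' @return Named list of [tissue_properties()] keyed by label ("1".."6"),
#'   with a `names` attribute-like element `$labels` mapping label -> name.
#' @export
default_tissue_table <- function() {
  f <- round(exp(seq(log(50), log(7500), length.out = 8)), 2)
  gm_eps <- c(4.1e7, 1.9e7, 8.7e6, 4.0e6, 1.8e6, 8.3e5, 3.8e5, 1.8e5)
  tab <- list(
    "1" = tissue_properties("skin", f, rep(0.10, 8), rep(1136, 8) * c(8, 6, 4.5, 3.4, 2.5, 1.9, 1.4, 1)),
    "2" = tissue_properties("skull", f, rep(0.020, 8), c(5.9e3, 4.9e3, 4.1e3, 3.4e3, 2.8e3, 2.4e3, 2.0e3, 1.7e3)),
    "3" = tissue_properties("csf", f, rep(1.79, 8), rep(109, 8)),
    "4" = tissue_properties("grey_matter", f,
                            c(0.075, 0.078, 0.082, 0.086, 0.091, 0.096, 0.102, 0.108),
                            gm_eps),
    "5" = tissue_properties("white_matter", f,
                            c(0.053, 0.055, 0.058, 0.060, 0.063, 0.066, 0.069, 0.072),
                            c(2.9e7, 1.3e7, 5.9e6, 2.7e6, 1.2e6, 5.5e5, 2.5e5, 1.2e5)),
    NULL
  )
  tab <- tab[!vapply(tab, is.null, logical(1))]
  tab[["6"]] <- edema_properties(tab[["4"]])
  tab
}

#' Electrical properties of ischemic edema
#'
#' The edematous lesion is assigned a frequency-independent conductivity of
#' 1.7 S/m and the relative permittivity of grey matter.
#'
#' @param grey_matter_props [tissue_properties()] of grey matter.
#' @param sigma_S_per_m Constant conductivity (default 1.7 S/m).
#' @return [tissue_properties()] named "edema".
#' @export
edema_properties <- function(grey_matter_props, sigma_S_per_m = 1.7) {
  tissue_properties("edema", grey_matter_props$f_hz,
                    rep(sigma_S_per_m, length(grey_matter_props$f_hz)),
                    grey_matter_props$eps_r_tab)
}

#' Read a tissue property table from CSV
#'
#' Long format with columns `label`, `name`, `f_hz`, `sigma_S_per_m`,
#' `eps_r`; one row per tissue per tabulated frequency.
#' @param path CSV file path.
#' @return Named list of [tissue_properties()] keyed by label.
#' @export
read_tissue_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "name", "f_hz", "sigma_S_per_m", "eps_r")
  if (!all(need %in% names(df)))
    stopf("tissue table %s must have columns: %s", path, paste(need, collapse = ", "))
  out <- list()
  for (lb in unique(df$label)) {
    sub <- df[df$label == lb, ]
    out[[as.character(lb)]] <- tissue_properties(sub$name[1], sub$f_hz,
                                                 sub$sigma_S_per_m, sub$eps_r)
  }
  out
}

#' Write a tissue table to CSV (inverse of [read_tissue_table()])
#' @param table Named list of [tissue_properties()].
#' @param path Output CSV path.
#' @export
write_tissue_table <- function(table, path) {
  rows <- do.call(rbind, lapply(names(table), function(lb) {
    p <- table[[lb]]
    data.frame(label = as.integer(lb), name = p$name, f_hz = p$f_hz,
               sigma_S_per_m = p$sigma_S_per_m, eps_r = p$eps_r_tab)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
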