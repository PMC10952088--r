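# broom-style tidiers: tidy() returns the per-observation table of a result
# object, glance() the one-row summary.

#' @export
tidy.aq_rdf <- function(x, ...) x$data

#' @export
glance.aq_rdf <- function(x, ...) {
  tibble::tibble(pair = x$pair, bin_width = x$bin_width, r_max = x$r_max,
                 rho = x$rho, n_frames = x$n_frames,
                 exclude_intramolecular = x$exclude_intramolecular)
}

#' @export
glance.aq_peaks <- function(x, ...) {
  tibble::tibble(pair = x$pair, r_max1 = x$r_max1, g_max1 = x$g_max1,
                 r_min1 = x$r_min1, g_min1 = x$g_min1, r_c = x$r_c,
                 temperature = x$temperature)
}

#' @export
tidy.aq_hbond <- function(x, ...) {
  nf <- nrow(x$total)
  nm <- ncol(x$total)
  tibble::tibble(frame = rep(x$frames, nm),
                 molecule = rep(seq_len(nm), each = nf),
                 n_donated = as.vector(x$donated),
                 n_accepted = as.vector(x$accepted),
                 n_total = as.vector(x$total))
}

#' @export
glance.aq_hbond <- function(x, ...) {
  tibble::tibble(h = x$h, h_donated = x$h_donated,
                 n_frames = length(x$frames), n_mol = ncol(x$total))
}

#' @export
tidy.aq_angledist <- function(x, ...) x$data

#' @export
glance.aq_angledist <- function(x, ...) {
  tibble::tibble(n_pairs = x$n_pairs, cutoff_OO = x$cutoff_OO,
                 cutoff_HO = x$cutoff_HO,
                 beta_mean = if (x$n_pairs > 0) mean(x$beta_values)
                             else NA_real_)
}

#' @export
tidy.aq_msd <- function(x, ...) x$data

#' @export
glance.aq_diffusion <- function(x, ...) {
  tibble::tibble(D_L = x$D_L, D_L_se = x$D_L_se,
                 D_L_1e9m2s = x$D_L_1e9m2s, D_inf = x$D_inf,
                 D_inf_1e9m2s = x$D_inf_1e9m2s,
                 fit_start = x$fit_window[1], fit_end = x$fit_window[2],
                 n_points = x$n_points)
}

#' @export
tidy.aq_acf <- function(x, ...) x$data

#' @export
glance.aq_relax <- function(x, ...) {
  tibble::tibble(tau = x$tau, A = x$A, axis = x$axis, order = x$order,
                 residual = x$residual, n_points = x$n_points,
                 short_trajectory = x$short_trajectory)
}

#' @export
tidy.aq_volscan <- function(x, ...) x$data

#' @export
glance.aq_volscan <- function(x, ...) {
  tibble::tibble(v_eq = x$v_eq, e_min = x$e_min, bracketed = x$bracketed,
                 n_points = nrow(x$data))
}

#' @export
tidy.aq_density <- function(x, ...) x$data

#' @export
glance.aq_density <- function(x, ...) {
  tibble::tibble(density = x$density, v_eq_mean = x$v_eq_mean,
                 n_mol = x$n_mol, molar_mass = x$molar_mass,
                 n_snapshots = nrow(x$data))
}

#' @export
tidy.aq_report <- function(x, ...) {
  rows <- list()
  add <- function(stage, quantity, value, unit) {
    if (length(value) == 1L && is.finite(value))
      rows[[length(rows) + 1L]] <<-
        tibble::tibble(stage = stage, quantity = quantity,
                       value = as.numeric(value), unit = unit)
  }
  res <- x$results
  if (!is.null(res$rdf) && res$rdf$ok) {
    v <- res$rdf$value
    add("rdf", "r_max1", v$peaks$r_max1, "Angstrom")
    add("rdf", "g_max1", v$peaks$g_max1, "")
    add("rdf", "r_min1", v$peaks$r_min1, "Angstrom")
    add("rdf", "g_min1", v$peaks$g_min1, "")
    add("rdf", "r_c", v$peaks$r_c, "Angstrom")
    add("rdf", "n_OO_r2g_min", v$n_OO_r2g, "molecules")
    add("rdf", "n_OO_g_min", v$n_OO_g, "molecules")
    if (!is.null(v$rescaled_298K))
      for (dn in names(v$rescaled_298K))
        add("rdf", paste0(dn, "_298K"), v$rescaled_298K[[dn]],
            if (grepl("^r_", dn)) "Angstrom" else "")
  }
  if (!is.null(res$hbond) && res$hbond$ok) {
    v <- res$hbond$value
    add("hbond", "h", v$stats$h, "bonds/molecule")
    add("hbond", "beta_mean",
        if (v$angles$n_pairs > 0) mean(v$angles$beta_values) else NA_real_,
        "degrees")
  }
  if (!is.null(res$diffusion) && res$diffusion$ok) {
    v <- res$diffusion$value$fit
    add("diffusion", "D_L", v$D_L, "Angstrom^2/ps")
    add("diffusion", "D_L", v$D_L_1e9m2s, "1e-9 m^2/s")
    add("diffusion", "D_inf", v$D_inf, "Angstrom^2/ps")
    add("diffusion", "D_inf", v$D_inf_1e9m2s, "1e-9 m^2/s")
  }
  if (!is.null(res$acf) && res$acf$ok) {
    for (nmx in names(res$acf$value)) {
      f <- res$acf$value[[nmx]]$fit
      if (!is.null(f)) add("acf", paste0("tau_", nmx), f$tau, "ps")
    }
  }
  if (!is.null(res$density) && res$density$ok)
    add("density", "density", res$density$value$density, "g/cm^3")
  if (length(rows) == 0L)
    return(tibble::tibble(stage = character(), quantity = character(),
                          value = numeric(), unit = character()))
  do.call(rbind, rows)
}
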