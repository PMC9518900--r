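## Coarse backbone-torsion statistical surfaces.  A 15 x 15 degree
## log-probability grid per residue class (general / glycine / proline),
## built once from a smooth mixture of wrapped 2-D Gaussians over the
## known Ramachandran basins, then interpolated with a periodic bicubic
## B-spline so the energy and its gradient are continuous everywhere.

rama_cache <- new.env(parent = emptyenv())

wrapped_gauss2 <- function(phi, psi, mu, sd) {
  ## wrapped bivariate normal density (3 images per axis suffice for the
  ## basin widths used here)
  d <- 0
  for (kx in -1:1) for (ky in -1:1) {
    d <- d + exp(-0.5 * (((phi - mu[1] + 360 * kx) / sd[1])^2 +
                           ((psi - mu[2] + 360 * ky) / sd[2])^2))
  }
  d / (2 * pi * sd[1] * sd[2])
}

rama_basins <- function(class) {
  switch(class,
    general = list(
      list(w = 0.45, mu = c(-63, -43), sd = c(14, 14)),   # alpha
      list(w = 0.35, mu = c(-120, 130), sd = c(22, 22)),  # beta
      list(w = 0.12, mu = c(-65, 145), sd = c(16, 16)),   # ppII
      list(w = 0.08, mu = c(57, 42), sd = c(11, 11))),    # alpha-L
    gly = list(
      list(w = 0.3, mu = c(-70, -40), sd = c(20, 20)),
      list(w = 0.3, mu = c(70, 40), sd = c(20, 20)),
      list(w = 0.2, mu = c(-100, 160), sd = c(25, 25)),
      list(w = 0.2, mu = c(100, -160), sd = c(25, 25))),
    pro = list(
      list(w = 0.5, mu = c(-63, -35), sd = c(9, 13)),
      list(w = 0.5, mu = c(-63, 145), sd = c(9, 15))),
    stop("unknown torsion table class: ", class))
}

#' Backbone-torsion energy grids
#'
#' Returns the shipped 15 x 15 degree torsion-energy tables (24 x 24
#' values at the bin centers -172.5, ..., 172.5 degrees) for the three
#' residue classes, as `-log` of a smooth basin mixture shifted so that
#' each table's minimum is zero.
#'
#' @return Named list of 24 x 24 matrices (`general`, `gly`, `pro`); rows
#'   index phi, columns psi.
#' @export
torsion_tables <- function() {
  if (!is.null(rama_cache$tables)) return(rama_cache$tables)
  centers <- seq(-172.5, 172.5, by = 15)
  grids <- lapply(c(general = "general", gly = "gly", pro = "pro"),
    function(class) {
      basins <- rama_basins(class)
      G <- matrix(0, 24, 24)
      for (i in 1:24) for (j in 1:24) {
        d <- 1e-4   # floor keeping disallowed regions finite
        for (b in basins)
          d <- d + b$w * wrapped_gauss2(centers[i], centers[j], b$mu, b$sd)
        G[i, j] <- -log(d)
      }
      G - min(G)
    })
  rama_cache$tables <- grids
  grids
}

torsion_table_coefficients <- function(tables = torsion_tables()) {
  if (!is.null(rama_cache$coefs)) return(rama_cache$coefs)
  P <- get_periodic_operator(24)
  co <- lapply(tables, function(G) P %*% G %*% t(P))
  rama_cache$coefs <- co
  co
}

torsion_table_index <- function(aa) {
  ## 0-based table index per residue for the compiled evaluator
  ifelse(aa == "G", 1L, ifelse(aa == "P", 2L, 0L))
}
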