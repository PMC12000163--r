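# Shared fixtures: the standard bench configurations used across tests.

ps5 <- function() particle_spec(radius = 5e-6, density = 1070)
hbmsc <- function() particle_spec(radius = 10.3e-6, density = 1062)

# 1 ml glass syringe barrel (R_S = 2.3 mm) and the slightly narrower
# geometry used for flow studies (R_S = 2.2 mm)
syr_1ml <- function(offset = 0)
  syringe_spec(2.3e-3, 40e-3, 0.5e-3, 5e-3, outlet_offset = offset)
syr_flow <- function(offset = 0)
  syringe_spec(2.2e-3, 40e-3, 0.5e-3, 5e-3, outlet_offset = offset)

# Monte-Carlo oracle for the area of {inside circle 1} /\ {region},
# sampling uniformly in a bounding box. Returns estimate and standard error.
mc_area <- function(n, xlim, ylim, predicate, seed = 424242) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x <- runif(n, xlim[1], xlim[2])
  y <- runif(n, ylim[1], ylim[2])
  box <- diff(xlim) * diff(ylim)
  hit <- predicate(x, y)
  list(area = mean(hit) * box,
       se = stats::sd(hit) * box / sqrt(n))
}
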