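# Shared fixtures, built in code. The tuning bank is cached inside the
# package, so repeated helper calls are cheap.

ORI <- v2pool::standard_orientations()

# raised-cosine tuning curve at preferred orientation `p`
cosine_tuning <- function(p, r0 = 1, a = 1) {
  r0 + a * cos(2 * (ORI - p) * pi / 180)
}

# small noiseless synthetic map, memoised per (side, seed)
.fixture_env <- new.env()
fixture_map <- function(side = 64, seed = 9, noise_sd = 0) {
  key <- paste(side, seed, noise_sd, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    cfg <- map_sim_config(side, side, noise_sd = noise_sd, seed = seed)
    .fixture_env[[key]] <- simulate_orientation_map(cfg)
  }
  .fixture_env[[key]]
}

fixture_bank <- function() aspect_ratio_bank(res = 0.05)

# model V1 population on an even PO grid with gammas cycling over the bank
fixture_v1_population <- function(n_cells, gamma_min = 0.5) {
  bank <- fixture_bank()
  po <- seq(0, 180, length.out = n_cells + 1)[-(n_cells + 1)]
  gam <- rep(bank$gammas[bank$gammas >= gamma_min], length.out = n_cells)
  gidx <- match(gam, bank$gammas)
  model <- t(vapply(seq_len(n_cells), function(i) {
    v2pool:::bank_tuning(bank, gidx[i], po[i])
  }, numeric(8)))
  measured <- t(vapply(po, cosine_tuning, numeric(8), r0 = 50, a = 40))
  list(po = po, gamma = gam, model = model, measured = measured)
}

# synthetic raw response stack realising the given single-condition maps:
# baseline 100, evoked window 100 - response, constant control image
fixture_stack <- function(responses) {
  h <- dim(responses)[1]; w <- dim(responses)[2]
  ors <- c(0, rep(ORI, each = 2))
  dat <- array(100, c(length(ors), 20, h, w))
  for (t in seq_along(ors)) {
    k <- match(ors[t], ORI)
    for (f in 15:20) dat[t, f, , ] <- 100 - responses[, , k]
  }
  response_stack(dat, ors)
}

# map with a linear (one-dimensional) PO gradient; exact cosine tuning
fixture_gradient_map <- function(h = 96, w = 96, cycles = 2) {
  po <- matrix(seq(0, cycles * 180, length.out = w) %% 180, h, w, byrow = TRUE)
  responses <- array(0, c(h, w, 8))
  for (k in 1:8) {
    responses[, , k] <- 50 + 40 * cos(2 * (ORI[k] - po) * pi / 180)
  }
  list(po = po, responses = responses)
}
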