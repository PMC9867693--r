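# Internal helpers shared across modules.

KM_PER_DEG_LAT <- 110.574

km_per_deg_lon <- function(lat) 111.320 * cos(lat * pi / 180)

# Planar offsets (km) of points from a local origin under an equirectangular
# projection centred on the origin; adequate well below ~10 km scales.
local_km_offsets <- function(lat, lon, lat0, lon0) {
  list(
    dx = (lon - lon0) * km_per_deg_lon(lat0),
    dy = (lat - lat0) * KM_PER_DEG_LAT
  )
}

# "HH:MM:SS" (or "HH:MM") -> seconds since local midnight.
parse_hms <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) < 2L || anyNA(suppressWarnings(as.numeric(p)))) {
      return(NA_real_)
    }
    p <- as.numeric(p)
    p[1] * 3600 + p[2] * 60 + if (length(p) >= 3) p[3] else 0
  }, numeric(1))
}

format_hms <- function(sec) {
  sec <- round(sec)
  sprintf("%02d:%02d:%02d", sec %/% 3600, (sec %% 3600) %/% 60, sec %% 60)
}

# Zero-truncated Poisson draws; guarantees counts >= 1 even for tiny lambda.
rztpois <- function(n, lambda) {
  lambda <- pmax(lambda, 1e-12)
  u <- runif(n, exp(-lambda), 1)
  pmax(1L, qpois(u, lambda))
}

# Derive a stream of independent sub-seeds from one master seed, keeping each
# below .Machine$integer.max.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

stop_stage <- function(stage, msg, ...) {
  abort(paste0("[", stage, "] ", sprintf(msg, ...)), class = "checkrich_stage_error")
}
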