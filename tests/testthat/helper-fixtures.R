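# Shared fixture builders. Everything is generated in code; no binary
# fixtures on disk.

# a bare protrusion geometry for constructed-track tests
make_geom <- function(base, tip, area = 10L, perimeter = 20,
                      width = 6) {
  list(label = 1L, area_px = as.integer(area), perimeter_px = perimeter,
       base_xy = base, tip_xy = tip, tip_radius_px = width / 2,
       euclidean_D = sqrt(sum((tip - base)^2)), width_w_px = width,
       flagged = FALSE)
}

make_track <- function(bases, tips, frames = seq_along(bases),
                       track_id = 1L) {
  list(track_id = track_id, frames = as.integer(frames),
       geoms = Map(make_geom, bases, tips),
       pixels = replicate(length(frames), integer(0), simplify = FALSE))
}

# binary disk mask
disk_mask <- function(nr, nc, center, radius) {
  outer(seq_len(nr), seq_len(nc), function(r, c)
    (r - center[1])^2 + (c - center[2])^2 <= radius^2)
}

# disk body + axis-aligned rectangular protrusions
disk_with_arms <- function(nr = 120, nc = 120, center = c(60, 60),
                           radius = 30, arms = list()) {
  m <- disk_mask(nr, nc, center, radius)
  for (a in arms) {
    # a: list(dir = "E"/"N"/..., width, length)
    h <- (a$width - 1) %/% 2
    if (a$dir == "E") {
      m[(center[1] - h):(center[1] + h),
        center[2]:(center[2] + radius + a$length)] <- TRUE
    } else if (a$dir == "W") {
      m[(center[1] - h):(center[1] + h),
        (center[2] - radius - a$length):center[2]] <- TRUE
    } else if (a$dir == "N") {
      m[(center[1] - radius - a$length):center[1],
        (center[2] - h):(center[2] + h)] <- TRUE
    } else {
      m[center[1]:(center[1] + radius + a$length),
        (center[2] - h):(center[2] + h)] <- TRUE
    }
  }
  m
}

# single-capsule movie spec for length-oracle tests
capsule_spec <- function(length_um, angle_deg, seed, width_px = 6,
                         noise_sd = 2) {
  side <- 2 * (ceiling(length_um * 1000 / 65) + 60)
  movie_spec(width = side, height = side, n_frames = 1, seed = seed,
             noise_sd = noise_sd, body_radius_px = 30,
             filopodia = list(list(angle_deg = angle_deg,
                                   velocity_nm_s = 0,
                                   initial_length_um = length_um,
                                   width_px = width_px)))
}

# paired decoupled/coupled series lists for the statistics layer
coupled_dataset <- function(K, n, coupling, seed0, ar_coeff = 0.6) {
  f <- vector("list", K); m <- vector("list", K)
  for (i in seq_len(K)) {
    cs <- generate_coupled_series(n, coupling = coupling,
                                  ar_coeff = ar_coeff, seed = seed0 + i)
    f[[i]] <- cs$fluorescence
    m[[i]] <- cs$movement
  }
  list(fluor = f, dctm = m)
}

# brute-force minimal assignment cost by permutation enumeration
brute_force_assignment_cost <- function(C) {
  n <- nrow(C)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  min(vapply(perms(seq_len(n)), function(p)
    sum(C[cbind(seq_len(n), p)]), 0))
}

# reference segmentation parameters used across tests
test_sparams <- function(...) segmentation_params(...)
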