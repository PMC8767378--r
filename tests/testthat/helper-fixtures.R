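# Shared test fixtures: tiny populations and a small render configuration
# (96 px frames keep rendering and CNN passes fast).

small_render_cfg <- function(channels = 1)
  render_config(image_size = c(96, 96), channels = channels, noise_sd = 0.01)

tiny_population <- function(n = 6, seed = 42, ...)
  sample_population(population_params(n, seed = seed, ...))

# a complete, valid frontal landmark set (hand-placed, symmetric)
symmetric_frontal_set <- function(subject_id = "T1") {
  mid <- 112
  pts <- rbind(
    g = c(mid, 40), n = c(mid, 60), prn = c(mid, 95), sn = c(mid, 110),
    pg = c(mid, 150), gn = c(mid, 165),
    en_R = c(mid - 18, 52), en_L = c(mid + 18, 52),
    ex_R = c(mid - 45, 51), ex_L = c(mid + 45, 51),
    mf_R = c(mid - 9, 56), mf_L = c(mid + 9, 56),
    al_R = c(mid - 20, 97), al_L = c(mid + 20, 97),
    mal_R = c(mid - 16, 101), mal_L = c(mid + 16, 101),
    ac_R = c(mid - 16, 108), ac_L = c(mid + 16, 108),
    zy_R = c(mid - 70, 70), zy_L = c(mid + 70, 70),
    ch_R = c(mid - 24, 130), ch_L = c(mid + 24, 130))
  landmark_set(subject_id, "frontal", pts)
}

# bone profile with a constructed hump of height h (mm) at the chord midpoint
humped_profile <- function(h, sr = 18, ns = 5.7) {
  d <- c(cos(pi / 6), sin(pi / 6))
  n <- c(0, 0)
  s <- n + ns * d + c(-d[2], d[1])
  r <- s + sr * d
  ant <- c(d[2], -d[1])
  k <- s + (sr / 2) * d + h * ant
  prn <- r + 8 * c(cos(55 * pi / 180), sin(55 * pi / 180))
  bone_profile(rbind(n = n, s = s, k = k, r = r, prn = prn))
}
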