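# Shared fixtures and independent oracles, built in code at test time.

# A fast noise-free single-cell phantom spec.
quiet_spec <- function(E = 8, ...) {
  phantom_spec(probes = list(
    list(name = "PM", membrane_density = 1, enrichment = 1,
         cyto_density = 0.05, lysosome_density = 0),
    list(name = "D4H", membrane_density = 1, enrichment = E,
         cyto_density = 0.05, lysosome_density = 0)),
    poisson = FALSE, read_sd = 0, psf_sigma_um = 0, ...)
}

noisy_spec <- function(E = 8, ...) {
  phantom_spec(probes = list(
    list(name = "PM", membrane_density = 1, enrichment = 1,
         cyto_density = 0.05, lysosome_density = 0),
    list(name = "D4H", membrane_density = 1, enrichment = E,
         cyto_density = 0.05, lysosome_density = 0)), ...)
}

# Reduced-geometry variants for fast tests (cell shrunk to fit small stacks).
small_geom <- list(cell_semiaxes_um = c(1.8, 1.2, 1.2), membrane_um = 0.3,
                   stereocilia_count = 8, stereocilia_radius_um = 0.25,
                   stereocilia_length_um = 1.5, stack_shape = c(48, 32, 32),
                   voxel_size_um = c(0.12, 0.1, 0.1))

small_quiet_spec <- function(E = 8, ...)
  do.call(quiet_spec, utils::modifyList(c(list(E = E), small_geom), list(...)))

small_noisy_spec <- function(E = 8, ...)
  do.call(noisy_spec, utils::modifyList(c(list(E = E), small_geom), list(...)))

# Voxelised sphere mask by center-of-voxel inclusion.
sphere_mask <- function(diameter_um, voxel_um, pad_vox = 4) {
  r <- diameter_um / 2
  n <- ceiling(diameter_um / voxel_um) + 2 * pad_vox
  ctr <- n / 2 * voxel_um
  ax <- (seq_len(n) - 0.5) * voxel_um
  d2 <- outer(outer((ax - ctr)^2, (ax - ctr)^2, `+`), (ax - ctr)^2, `+`)
  array(d2 <= r^2, dim = c(n, n, n))
}

# Independent Fisher oracle: direct choose() enumeration over the support.
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, function(i)
    choose(m, i) * choose(n, k - i) / choose(m + n, k), 0)
  p_obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Independent pattern-scan oracle: test every start by direct set membership.
scan_oracle <- function(pattern, sequences) {
  sets <- lapply(pattern$positions, function(p) p$residues)
  Lp <- length(sets)
  rows <- list()
  for (si in seq_along(sequences)) {
    chars <- strsplit(sequences[[si]], "")[[1]]
    n <- length(chars)
    if (Lp > n) next
    for (st in 1:(n - Lp + 1)) {
      hit <- TRUE
      for (p in 1:Lp) if (!(chars[st + p - 1] %in% sets[[p]])) { hit <- FALSE; break }
      if (hit) rows[[length(rows) + 1L]] <-
          data.frame(seq_id = names(sequences)[si], start = st,
                     end = st + Lp - 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(seq_id = character(0), start = integer(0),
                                       end = integer(0)))
  do.call(rbind, rows)
}

# Random fixed-length pattern over literals, sets and classes.
random_pattern <- function(len, table = residue_class_table()) {
  pos <- lapply(seq_len(len), function(i) {
    kind <- sample(c("literal", "set", "class", "wildcard"), 1,
                   prob = c(0.3, 0.3, 0.3, 0.1))
    switch(kind,
           literal = sample(bundlequant:::AA20, 1),
           set = paste0("[", paste(sample(bundlequant:::AA20, 2), collapse = ""), "]"),
           class = paste0("[", sample(c("Omega", "Psi", "pi", "zeta", "Phi"), 1), "]"),
           wildcard = "x")
  })
  parse_pattern(paste(unlist(pos), collapse = "-"), table)
}

random_protein <- function(len) paste(sample(bundlequant:::AA20, len,
                                             replace = TRUE), collapse = "")
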