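# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# exact area-weighted mean of raster values under an axis-aligned rectangle
# (analytic rectangle-pixel intersection, no grid refinement)
rect_weighted_oracle <- function(r, xmin, xmax, ymin, ymax) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  ytop <- r$ymin + nr * r$res
  tot_w <- 0; tot_v <- 0
  for (i in seq_len(nr)) {
    py1 <- ytop - i * r$res; py2 <- ytop - (i - 1) * r$res
    oy <- max(0, min(ymax, py2) - max(ymin, py1))
    if (oy == 0) next
    for (j in seq_len(nc)) {
      px1 <- r$xmin + (j - 1) * r$res; px2 <- r$xmin + j * r$res
      ox <- max(0, min(xmax, px2) - max(xmin, px1))
      if (ox == 0) next
      tot_w <- tot_w + ox * oy
      tot_v <- tot_v + ox * oy * r$values[i, j]
    }
  }
  tot_v / tot_w
}

# brute-force rarefaction: enumerate all size-n subsets of individuals
rarefy_brute <- function(counts, n) {
  labels <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(labels), n)
  mean(apply(subs, 2, function(ix) length(unique(labels[ix]))))
}

# tiny stem table builder for inventory tests
make_stems <- function(species, dbh, status = "live", subplot = "sp001",
                       mode = "none", resprouter = FALSE,
                       pool = default_species_pool()) {
  idx <- match(species, pool$species)
  genus <- ifelse(is.na(idx), sub(" .*", "", species), pool$genus[idx])
  gidx <- match(genus, pool$genus)
  tibble::tibble(
    tree_id = sprintf("t%03d", seq_along(species)),
    subplot_id = rep_len(subplot, length(species)),
    species = species,
    genus = genus,
    family = ifelse(is.na(gidx), NA_character_, pool$family[gidx]),
    dbh_cm = dbh,
    status = rep_len(status, length(species)),
    mode_of_death = rep_len(mode, length(species)),
    resprouter = rep_len(resprouter, length(species)),
    wood_density = ifelse(is.na(idx), NA_real_, pool$wood_density[idx])
  )
}

one_subplot <- function(area = 250) {
  tibble::tibble(subplot_id = "sp001", area_m2 = area)
}

# small deterministic synthetic bundle shared by several test files
tiny_world <- function(seed = 7, noise = 0, n = 60, count = 40) {
  lp <- landscape_params(nrows = n, ncols = n, noise_sd = noise,
                         seed = seed)
  topo <- generate_topography(lp)
  tm <- generate_true_mortality(topo, lp)
  sc <- synthesize_scene_pair(tm, noise_sd = noise, seed = seed + 50)
  d <- delta_npv(shade_normalize(unmix_scene(sc$pre)),
                 shade_normalize(unmix_scene(sc$post)))
  sp <- subplot_true_mortality(generate_subplots(topo, count = count), tm)
  list(lp = lp, topo = topo, tm = tm, scenes = sc, dnpv = d,
       subplots = sp)
}
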