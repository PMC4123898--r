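#' Default synthetic species pool
#'
#' 60 species (morphotypes) in 25 genera and 15 families typical of
#' Central Amazon terra-firme forest, including the regional
#' light-demanding pioneer genera (Cecropia, Conceveiba, Inga, Laetia,
#' Miconia, Pourouma, Tachigali, Vismia). Pioneer wood densities span
#' 0.30-0.50 g cm-3, strictly below the pool median; late-successional
#' species span 0.55-0.92 g cm-3.
#'
#' @return Tibble: `species`, `genus`, `family`, `wood_density`, `pioneer`.
#' @export
default_species_pool <- function() {
  gen <- tibble::tribble(
    ~genus, ~family, ~pioneer, ~n_sp,
    "Cecropia", "Urticaceae", TRUE, 2L,
    "Conceveiba", "Euphorbiaceae", TRUE, 1L,
    "Inga", "Fabaceae", TRUE, 4L,
    "Laetia", "Salicaceae", TRUE, 1L,
    "Miconia", "Melastomataceae", TRUE, 3L,
    "Pourouma", "Urticaceae", TRUE, 2L,
    "Tachigali", "Fabaceae", TRUE, 2L,
    "Vismia", "Hypericaceae", TRUE, 2L,
    "Eschweilera", "Lecythidaceae", FALSE, 6L,
    "Corythophora", "Lecythidaceae", FALSE, 1L,
    "Couratari", "Lecythidaceae", FALSE, 2L,
    "Pouteria", "Sapotaceae", FALSE, 5L,
    "Micropholis", "Sapotaceae", FALSE, 2L,
    "Licania", "Chrysobalanaceae", FALSE, 4L,
    "Protium", "Burseraceae", FALSE, 4L,
    "Ocotea", "Lauraceae", FALSE, 3L,
    "Swartzia", "Fabaceae", FALSE, 3L,
    "Virola", "Myristicaceae", FALSE, 2L,
    "Iryanthera", "Myristicaceae", FALSE, 2L,
    "Brosimum", "Moraceae", FALSE, 2L,
    "Naucleopsis", "Moraceae", FALSE, 1L,
    "Guatteria", "Annonaceae", FALSE, 2L,
    "Duguetia", "Annonaceae", FALSE, 1L,
    "Goupia", "Goupiaceae", FALSE, 1L,
    "Micrandra", "Euphorbiaceae", FALSE, 2L
  )
  pool <- tidyr::uncount(gen, weights = .data$n_sp, .id = "sp_no")
  pool$species <- sprintf("%s sp%02d", pool$genus, pool$sp_no)
  # late-successional species first so log-series ranks make them common
  pool <- dplyr::arrange(pool, .data$pioneer)
  pool$wood_density <- NA_real_
  pool$wood_density[!pool$pioneer] <-
    seq(0.55, 0.92, length.out = sum(!pool$pioneer))
  pool$wood_density[pool$pioneer] <-
    seq(0.30, 0.50, length.out = sum(pool$pioneer))
  pool[, c("species", "genus", "family", "wood_density", "pioneer")]
}

#' The pioneer genus list
#'
#' Light-demanding, fast-growing genera typical for the region; a stem is
#' treated as a pioneer recruit only when its genus is in this list and
#' its DBH does not exceed 25 cm (see [pioneer_metrics()]).
#' @export
default_pioneer_genera <- function() {
  c("Cecropia", "Conceveiba", "Inga", "Laetia", "Miconia", "Pourouma",
    "Tachigali", "Vismia")
}

#' Parameters for the synthetic stem-table generator
#'
#' Defaults reproduce the undisturbed baseline of the study system:
#' 583 trees per hectare, 26.7 m2 per hectare basal area over stems with
#' DBH >= 10 cm. The DBH distribution is `10 + Exponential(mean mu)` with
#' `mu` derived so that expected basal area per stem matches
#' `baseline_basal_area / baseline_density`.
#'
#' @param baseline_density Live trees per hectare before disturbance.
#' @param baseline_basal_area Basal area, m2 per hectare.
#' @param species_pool Tibble as from [default_species_pool()].
#' @param logseries_x Log-series abundance parameter in (0, 1); rank-k
#'   species get weight `x^k / k`.
#' @param pioneer_gain Pioneer recruitment intensity: recruits per subplot
#'   have mean `pioneer_gain * m * baseline_density * area` at mortality
#'   fraction `m`.
#' @param resprout_gain Slope of resprouter probability on mortality.
#' @param resprout_base Baseline resprouter probability at zero mortality.
#' @param recruit_dbh_mean Mean of the recruit DBH excess over 10 cm.
#' @return A `bd_community_params` list (with the derived `dbh_mean_excess`).
#' @export
community_params <- function(baseline_density = 583,
                             baseline_basal_area = 26.7,
                             species_pool = default_species_pool(),
                             logseries_x = 0.97,
                             pioneer_gain = 0.8,
                             resprout_gain = 0.5,
                             resprout_base = 0.02,
                             recruit_dbh_mean = 4) {
  stopifnot(baseline_density > 0, baseline_basal_area > 0,
            pioneer_gain >= 0, resprout_gain >= 0,
            logseries_x > 0, logseries_x < 1)
  if (nrow(species_pool) == 0) stop("species pool is empty")
  if (any(species_pool$wood_density <= 0)) {
    stop("all wood densities must be positive")
  }
  # E[dbh^2] (cm^2) implied by mean stem basal area; dbh = 10 + Exp(mu)
  # gives E[dbh^2] = 100 + 20 mu + 2 mu^2, solved for mu
  ed2 <- baseline_basal_area / baseline_density * 4e4 / pi
  if (ed2 <= 100) stop("basal area too small for the 10 cm DBH floor")
  mu <- (-20 + sqrt(400 - 8 * (100 - ed2))) / 4
  structure(
    list(baseline_density = baseline_density,
         baseline_basal_area = baseline_basal_area,
         species_pool = species_pool, logseries_x = logseries_x,
         pioneer_gain = pioneer_gain, resprout_gain = resprout_gain,
         resprout_base = resprout_base,
         recruit_dbh_mean = recruit_dbh_mean,
         dbh_mean_excess = mu),
    class = "bd_community_params"
  )
}

logseries_weights <- function(n, x) {
  k <- seq_len(n)
  w <- x^k / k
  w / sum(w)
}

# class-dependent mode-of-death mixture: uprooting/snapping enriched on
# slopes, standing death on plateaus
death_mode_probs <- function(topo_class) {
  switch(topo_class,
         plateau = c(snapped = 0.30, uprooted = 0.25, standing = 0.45),
         slope = c(snapped = 0.35, uprooted = 0.45, standing = 0.20),
         c(snapped = 0.30, uprooted = 0.35, standing = 0.35))
}

#' Generate a synthetic stem census
#'
#' For each sub-plot with true mortality fraction `m`: surviving stems are
#' Poisson with mean `density * area * (1 - m)` drawn from the log-series
#' pool; pioneer recruits are Poisson with mean
#' `pioneer_gain * m * density * area` drawn from the pioneer species;
#' dead stems are Poisson with mean `density * area * m` with
#' class-dependent modes of death; live stems carry a resprouter flag with
#' probability `resprout_base + resprout_gain * m`. All DBH >= 10 cm.
#'
#' @param subplots Sub-plot tibble carrying `subplot_id`, `area_m2`,
#'   `topo_class` and `true_mortality` (see [subplot_true_mortality()]).
#' @param cparams A [community_params()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @return List: `stems` (tibble with `tree_id`, `subplot_id`, `species`,
#'   `genus`, `family`, `dbh_cm`, `status`, `mode_of_death`, `resprouter`,
#'   `wood_density`) and `truth` (per-sub-plot true mortality, expected
#'   pioneer fraction and resprouter probability).
#' @export
generate_stem_table <- function(subplots, cparams = community_params(),
                                seed = 1L) {
  stopifnot(inherits(cparams, "bd_community_params"))
  if (!"true_mortality" %in% names(subplots)) {
    stop("subplots must carry true_mortality (see subplot_true_mortality())")
  }
  if (any(subplots$true_mortality < 0 | subplots$true_mortality > 1)) {
    stop("true mortalities must lie in [0, 1]")
  }
  pool <- cparams$species_pool
  w_all <- logseries_weights(nrow(pool), cparams$logseries_x)
  pio <- which(pool$pioneer)
  if (!length(pio)) stop("species pool contains no pioneer species")
  w_pio <- w_all[pio] / sum(w_all[pio])
  dens <- cparams$baseline_density
  mu <- cparams$dbh_mean_excess

  stems <- with_local_seed(seed, {
    purrr::map(seq_len(nrow(subplots)), function(i) {
      sp <- subplots[i, ]
      m <- sp$true_mortality
      a <- sp$area_m2 / 1e4
      n_surv <- rpois(1, dens * a * (1 - m))
      n_rec <- rpois(1, cparams$pioneer_gain * m * dens * a)
      n_dead <- rpois(1, dens * a * m)
      idx_live <- c(
        sample.int(nrow(pool), n_surv, replace = TRUE, prob = w_all),
        pio[sample.int(length(pio), n_rec, replace = TRUE, prob = w_pio)]
      )
      idx_dead <- sample.int(nrow(pool), n_dead, replace = TRUE,
                             prob = w_all)
      dbh <- c(10 + stats::rexp(n_surv, 1 / mu),
               10 + stats::rexp(n_rec, 1 / cparams$recruit_dbh_mean),
               10 + stats::rexp(n_dead, 1 / mu))
      idx <- c(idx_live, idx_dead)
      n_live <- n_surv + n_rec
      status <- rep(c("live", "dead"), c(n_live, n_dead))
      pm <- death_mode_probs(sp$topo_class)
      mode <- c(rep("none", n_live),
                sample(names(pm), n_dead, replace = TRUE, prob = pm))
      p_res <- min(1, cparams$resprout_base + cparams$resprout_gain * m)
      resp <- c(runif(n_live) < p_res, rep(FALSE, n_dead))
      tibble::tibble(
        tree_id = sprintf("%s_t%03d", sp$subplot_id, seq_along(idx)),
        subplot_id = sp$subplot_id,
        species = pool$species[idx],
        genus = pool$genus[idx],
        family = pool$family[idx],
        dbh_cm = dbh,
        status = status,
        mode_of_death = mode,
        resprouter = resp,
        wood_density = pool$wood_density[idx]
      )
    })
  })

  base_pio_share <- sum(w_all[pio])
  m <- subplots$true_mortality
  truth <- tibble::tibble(
    subplot_id = subplots$subplot_id,
    true_mortality = m,
    expected_pioneer_fraction =
      (cparams$pioneer_gain * m + base_pio_share * (1 - m)) /
      pmax(1e-12, cparams$pioneer_gain * m + (1 - m)),
    resprouter_prob = pmin(1, cparams$resprout_base +
                             cparams$resprout_gain * m)
  )
  list(stems = dplyr::bind_rows(stems), truth = truth)
}

#' Simulate a complete blowdown study
#'
#' End-to-end synthetic study: topography, true mortality field, pre/post
#' reflectance scene pair, sub-plot layout with per-plot ground truth, and
#' the stem census. Every stage is seeded from `lparams$seed` (scenes and
#' stems use fixed offsets of it), so the bundle is reproducible.
#'
#' @param lparams A [landscape_params()].
#' @param cparams A [community_params()].
#' @param model A [mortality_model()].
#' @param lib An [endmember_library()].
#' @param subplot_count Number of field sub-plots (default 144).
#' @return List: `params`, `topo`, `true_mortality`, `scenes`
#'   (`$pre`/`$post`), `subplots` (with `true_mortality`), `stems`,
#'   `truth`.
#' @export
simulate_blowdown <- function(lparams = landscape_params(),
                              cparams = community_params(),
                              model = mortality_model(),
                              lib = default_endmembers(),
                              subplot_count = 144) {
  topo <- generate_topography(lparams)
  tm <- generate_true_mortality(topo, lparams)
  scenes <- synthesize_scene_pair(tm, lib, model,
                                  noise_sd = lparams$noise_sd,
                                  seed = lparams$seed + 2L)
  subplots <- generate_subplots(topo, count = subplot_count)
  subplots <- subplot_true_mortality(subplots, tm)
  census <- generate_stem_table(subplots, cparams,
                                seed = lparams$seed + 3L)
  list(params = list(landscape = lparams, community = cparams,
                     model = model, endmembers = lib),
       topo = topo, true_mortality = tm, scenes = scenes,
       subplots = subplots, stems = census$stems, truth = census$truth)
}
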