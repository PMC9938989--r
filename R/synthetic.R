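# Synthetic-study generator. Emulates the sampling design and statistical
# structure the analyses assume: monthly March--November sampling over
# several years at river sites plus two treatment plants; a period-12
# seasonal oscillation of community composition in water and effluent but
# not sewage or sediment; effluent influence on river water decaying
# exponentially with distance downstream of the outfall; and a step-change
# intervention at a fixed date that reduces a labeled coliform-like taxon
# subset in the effluent-derived signal. Taxon dynamics are log-normal on
# the latent scale with multinomial read sampling.

#' Configuration for a synthetic study
#'
#' Defaults mirror the study design: 12 river sites plus two treatment
#' plants in two regions, monthly sampling March--November (winters
#' unsampled, so the interpolation path is always exercised) over 7 years
#' starting 2013, an intervention at 2016-01 that reduces coliform-like
#' taxa in effluent about 20-fold, and effluent influence decaying per mile
#' downstream.
#'
#' @param n_taxa number of ASVs (>= 2)
#' @param n_sites number of river sites, split between the two regions
#' @param n_years number of sampled years
#' @param start_year first sampled year
#' @param months_sampled sampled month indices (default 3:11)
#' @param reads_per_sample multinomial read depth per sample
#' @param seasonal_amplitude sinusoid amplitude on the log-abundance scale
#'   applied to water/effluent taxa (0 = no seasonality)
#' @param seasonal_period oscillation period in months (default 12)
#' @param noise_sd per-sample, per-taxon log-abundance noise SD; also scales
#'   physicochemical measurement noise
#' @param effluent_mixing exponential decay coefficient (per mile) of
#'   effluent influence on downstream water
#' @param intervention_date `c(year, month)` of the treatment upgrade
#' @param intervention_log_reduction log-scale reduction applied to
#'   coliform-like taxa in effluent-derived signal from the intervention on
#'   (default `log(20)`, a ~20-fold drop)
#' @param coliform_taxon_fraction fraction of taxa labeled coliform-like
#' @param coliform_sdlog log-normal spread of the cultured coliform counts
#' @param seed integer seed; identical config gives an identical study
#' @return validated list of class `synthetic_config`
#' @export
synthetic_config <- function(n_taxa = 150L, n_sites = 12L, n_years = 7L,
                             start_year = 2013L, months_sampled = 3:11,
                             reads_per_sample = 2000L,
                             seasonal_amplitude = 3, seasonal_period = 12L,
                             noise_sd = 0.2, effluent_mixing = 1.0,
                             intervention_date = c(2016L, 1L),
                             intervention_log_reduction = log(20),
                             coliform_taxon_fraction = 0.05,
                             coliform_sdlog = 0.7, seed = 1L) {
  months_sampled <- sort(unique(as.integer(months_sampled)))
  if (length(months_sampled) == 0 || any(months_sampled < 1 | months_sampled > 12))
    stop("months_sampled must be a non-empty subset of 1..12", call. = FALSE)
  if (n_taxa < 2) stop("n_taxa must be >= 2", call. = FALSE)
  if (n_sites < 2) stop("n_sites must be >= 2", call. = FALSE)
  if (reads_per_sample < 1) stop("reads_per_sample must be >= 1", call. = FALSE)
  if (seasonal_period < 2) stop("seasonal_period must be >= 2", call. = FALSE)
  if (seasonal_amplitude < 0 || noise_sd < 0 || effluent_mixing < 0 ||
      intervention_log_reduction < 0)
    stop("amplitude, noise, mixing and reduction must be non-negative", call. = FALSE)
  if (coliform_taxon_fraction < 0 || coliform_taxon_fraction > 1)
    stop("coliform_taxon_fraction must be in [0, 1]", call. = FALSE)
  structure(list(
    n_taxa = as.integer(n_taxa), n_sites = as.integer(n_sites),
    n_years = as.integer(n_years), start_year = as.integer(start_year),
    months_sampled = months_sampled,
    reads_per_sample = as.integer(reads_per_sample),
    seasonal_amplitude = seasonal_amplitude,
    seasonal_period = as.integer(seasonal_period), noise_sd = noise_sd,
    effluent_mixing = effluent_mixing,
    intervention_date = as.integer(intervention_date),
    intervention_log_reduction = intervention_log_reduction,
    coliform_taxon_fraction = coliform_taxon_fraction,
    coliform_sdlog = coliform_sdlog, seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Site layout of a synthetic study
#'
#' Two regions, each with one treatment plant (effluent + sewage streams)
#' and river sites at fixed distances downstream of the outfall: one
#' upstream site (no effluent influence), one immediately downstream, one
#' further downstream, and any remaining sites still further along the
#' channel. Distances of the named roles follow the study's site map
#' (upstream 1.0/1.4 mi, immediate 1.3/0.7 mi, further 3.0/3.4 mi). The
#' mixing weight of a water site is exp(-effluent_mixing * distance), 0 for
#' upstream sites.
#'
#' @param config a [synthetic_config()]
#' @return data.frame: site_id, region, spatial_role, distance_miles,
#'   mixing_weight
#' @export
site_layout <- function(config) {
  regions <- c("Calumet", "OBrien")
  base_dist <- list(Calumet = c(upstream = 1.0, immediate_downstream = 1.3,
                                further_downstream = 3.0),
                    OBrien  = c(upstream = 1.4, immediate_downstream = 0.7,
                                further_downstream = 3.4))
  per_region <- c(ceiling(config$n_sites / 2), floor(config$n_sites / 2))
  rows <- list()
  for (r in 1:2) {
    reg <- regions[r]
    n <- per_region[r]
    roles <- c(names(base_dist[[reg]]),
               rep("other", max(0, n - 3)))[seq_len(n)]
    dist <- c(base_dist[[reg]],
              if (n > 3) base_dist[[reg]][3] + 2 * seq_len(n - 3))[seq_len(n)]
    rows[[reg]] <- data.frame(
      site_id = sprintf("%s_S%02d", reg, seq_len(n)),
      region = reg, spatial_role = roles, distance_miles = unname(dist),
      stringsAsFactors = FALSE)
    rows[[paste0(reg, "_wrp")]] <- data.frame(
      site_id = paste0(reg, "_WRP"), region = reg, spatial_role = "effluent",
      distance_miles = 0, stringsAsFactors = FALSE)
  }
  layout <- do.call(rbind, rows)
  rownames(layout) <- NULL
  layout$mixing_weight <- ifelse(
    layout$spatial_role == "effluent", 1,
    ifelse(layout$spatial_role == "upstream", 0,
           exp(-config$effluent_mixing * layout$distance_miles)))
  layout
}

#' Sampling frame (metadata skeleton) of a synthetic study
#'
#' One sample per site x sample-type stream x sampled (year, month): water
#' and sediment at every river site, effluent and sewage at each plant.
#'
#' @param config a [synthetic_config()]
#' @return sample metadata (see [as_sample_metadata()])
#' @export
study_metadata <- function(config) {
  layout <- site_layout(config)
  years <- config$start_year + seq_len(config$n_years) - 1L
  cal <- expand.grid(month = config$months_sampled, year = years,
                     KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  for (i in seq_len(nrow(layout))) {
    types <- if (layout$spatial_role[i] == "effluent") c("effluent", "sewage")
             else c("water", "sediment")
    for (ty in types) {
      rows[[paste(layout$site_id[i], ty)]] <- data.frame(
        sample_id = sprintf("%s.%s.%d.%02d", layout$site_id[i], ty,
                            cal$year, cal$month),
        site_id = layout$site_id[i], sample_type = ty,
        region = layout$region[i], spatial_role = layout$spatial_role[i],
        year = cal$year, month = cal$month, stringsAsFactors = FALSE)
    }
  }
  md <- do.call(rbind, rows)
  rownames(md) <- NULL
  as_sample_metadata(md, config$intervention_date)
}

#' Random rooted binary tree over the synthetic taxa
#'
#' Uniform random binary topology with branch lengths drawn from
#' U(0.05, 1); leaves named `ASV_0001`, ... Deterministic per
#' `(n_taxa, seed)`.
#'
#' @param n_taxa number of leaves (>= 2)
#' @param seed RNG seed
#' @return rooted [ape::phylo] tree
#' @export
generate_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 2) stop("n_taxa must be >= 2", call. = FALSE)
  tree <- with_seed(seed, ape::rtree(n_taxa, rooted = TRUE,
                                     br = function(n) stats::runif(n, 0.05, 1)))
  tree$tip.label <- sprintf("ASV_%04d", seq_len(n_taxa))
  tree
}

# Latent log-abundance model shared by generate_counts():
# log a_{s,t,taxon} = base + type offset + site offset
#                     + amplitude * sin(2 pi month / period + phase_taxon)
#                     + N(0, noise_sd)
# Water mixes the regional effluent composition (intervention applied there)
# with weight w = exp(-mixing * distance): p = w p_eff + (1-w) p_local.

#' Generate the synthetic count table and metadata
#'
#' See [synthetic_config()] for the generating model. The `truth` attribute
#' records, per (site, sample type), the seasonal amplitude, mixing weight
#' and intervention effect actually used, plus the per-taxon phases and the
#' coliform-like taxon ids -- enough for downstream modules to score
#' recovery.
#'
#' @param config a [synthetic_config()]
#' @return list with `table` (feature table), `metadata`, and `truth`
#' @export
generate_counts <- function(config) {
  md <- study_metadata(config)
  layout <- site_layout(config)
  taxa <- sprintf("ASV_%04d", seq_len(config$n_taxa))
  n_coliform <- ceiling(config$coliform_taxon_fraction * config$n_taxa)
  coliform <- taxa[seq_len(n_coliform)]
  cut <- ym_index(config$intervention_date[1], config$intervention_date[2])

  out <- with_seed(config$seed + 1L, {
    base_log <- stats::rnorm(config$n_taxa, 0, 1.5)
    phase <- stats::runif(config$n_taxa, 0, 2 * pi)
    type_off <- sapply(SAMPLE_TYPES, function(t) stats::rnorm(config$n_taxa, 0, 1))
    site_off <- sapply(layout$site_id, function(s) stats::rnorm(config$n_taxa, 0, 0.5))
    region_off <- sapply(c("Calumet", "OBrien"),
                         function(r) stats::rnorm(config$n_taxa, 0, 0.3))

    season <- function(month, amp)
      amp * sin(2 * pi * month / config$seasonal_period + phase)

    # deterministic effluent signal per (region, year, month); water inherits
    # the intervention through this signal, scaled by its mixing weight
    effluent_signal <- function(region, year, month) {
      lg <- base_log + type_off[, "effluent"] + region_off[, region] +
        season(month, config$seasonal_amplitude)
      if (ym_index(year, month) >= cut)
        lg[taxa %in% coliform] <- lg[taxa %in% coliform] -
          config$intervention_log_reduction
      p <- exp(lg)
      p / sum(p)
    }

    counts <- matrix(0L, nrow(md), config$n_taxa,
                     dimnames = list(md$sample_id, taxa))
    for (i in seq_len(nrow(md))) {
      ty <- md$sample_type[i]; site <- md$site_id[i]
      amp <- if (ty %in% c("water", "effluent")) config$seasonal_amplitude else 0
      lg <- base_log + type_off[, ty] + site_off[, site] + season(md$month[i], amp)
      lg <- lg + stats::rnorm(config$n_taxa, 0, config$noise_sd)
      p <- exp(lg); p <- p / sum(p)
      if (ty == "water") {
        w <- layout$mixing_weight[layout$site_id == site]
        p <- w * effluent_signal(md$region[i], md$year[i], md$month[i]) + (1 - w) * p
      }
      counts[i, ] <- stats::rmultinom(1, config$reads_per_sample, p)
    }
    list(counts = counts, phase = phase)
  })

  truth_rows <- unique(md[, c("site_id", "sample_type", "region", "spatial_role")])
  truth_rows$seasonal_amplitude <- ifelse(
    truth_rows$sample_type %in% c("water", "effluent"), config$seasonal_amplitude, 0)
  truth_rows$mixing_weight <- layout$mixing_weight[
    match(truth_rows$site_id, layout$site_id)]
  truth_rows$mixing_weight[truth_rows$sample_type != "water"] <-
    ifelse(truth_rows$sample_type[truth_rows$sample_type != "water"] == "effluent", 1, 0)
  truth_rows$intervention_effect <- ifelse(
    truth_rows$sample_type == "effluent", config$intervention_log_reduction,
    ifelse(truth_rows$sample_type == "water",
           config$intervention_log_reduction * truth_rows$mixing_weight, 0))
  rownames(truth_rows) <- NULL
  truth <- list(per_stream = truth_rows,
                phases = stats::setNames(out$phase, taxa),
                coliform_taxa = coliform)

  list(table = as_feature_table(out$counts), metadata = md, truth = truth)
}

#' Generate coliform and physicochemical measurement series
#'
#' Coliform CFU/100 mL are log-normal with a site-specific median that is
#' interpolated (on the log scale, by the site's mixing weight) between a
#' background river level and the pre-intervention effluent level; from the
#' intervention date the median drops by `intervention_log_reduction` scaled
#' by the mixing weight. Physicochemical variables are site offset +
#' seasonal sinusoid + Gaussian noise, with no intervention term.
#'
#' @param config a [synthetic_config()]
#' @param metadata sample metadata whose sites must come from this config's
#'   [site_layout()]
#' @return list with `coliform` (site_id, year, month, cfu_per_100ml) and
#'   `physchem` (variable, unit, site_id, year, month, value)
#' @export
generate_measurements <- function(config, metadata = NULL) {
  md <- metadata %||% study_metadata(config)
  if (nrow(md) == 0) stop("metadata is empty", call. = FALSE)
  layout <- site_layout(config)
  bad <- setdiff(unique(md$site_id), layout$site_id)
  if (length(bad) > 0)
    stop("unknown site in metadata: ", paste(bad, collapse = ", "), call. = FALSE)
  cut <- ym_index(config$intervention_date[1], config$intervention_date[2])

  cal <- unique(md[md$sample_type %in% c("water", "effluent"),
                   c("site_id", "year", "month")])
  cal <- cal[order(cal$site_id, ym_index(cal$year, cal$month)), ]
  w <- layout$mixing_weight[match(cal$site_id, layout$site_id)]
  log_bg <- log(500); log_eff <- log(12000)
  pre_logmed <- log_bg + w * (log_eff - log_bg)
  post <- ym_index(cal$year, cal$month) >= cut
  logmed <- pre_logmed - post * config$intervention_log_reduction * w

  pc_vars <- data.frame(
    variable = c("temperature", "pH", "dissolved_oxygen", "no2_no3", "nh3",
                 "total_phosphorus", "volatile_suspended_solids",
                 "total_organic_carbon", "conductivity", "turbidity",
                 "chlorophyll"),
    unit = c("degC", "pH", "mg/L", "mg/L", "mg/L", "mg/L", "mg/L", "mg/L",
             "mS", "NTU", "ug/L"),
    level = c(15, 7.6, 8, 4, 0.4, 0.7, 8, 9, 0.9, 12, 6),
    amplitude = c(10, 0.3, 3, 1, 0.15, 0.2, 3, 2, 0.15, 5, 4),
    stringsAsFactors = FALSE)
  # all variables peak in mid-summer (month ~7)
  pc_phase <- pi / 2 - 2 * pi * 7 / 12

  river <- layout$site_id[layout$spatial_role != "effluent"]
  pc_cal <- unique(md[md$site_id %in% river, c("site_id", "year", "month")])
  pc_cal <- pc_cal[order(pc_cal$site_id, ym_index(pc_cal$year, pc_cal$month)), ]

  with_seed(config$seed + 2L, {
    coliform <- data.frame(site_id = cal$site_id, year = cal$year,
                           month = cal$month,
                           cfu_per_100ml = stats::rlnorm(nrow(cal), logmed,
                                                         config$coliform_sdlog),
                           stringsAsFactors = FALSE)
    pc <- list()
    for (v in seq_len(nrow(pc_vars))) {
      off <- stats::setNames(stats::rnorm(length(river),
                                          0, 0.05 * abs(pc_vars$level[v])), river)
      val <- pc_vars$level[v] + off[pc_cal$site_id] +
        pc_vars$amplitude[v] * sin(2 * pi * pc_cal$month / 12 + pc_phase) +
        stats::rnorm(nrow(pc_cal), 0, config$noise_sd * pc_vars$amplitude[v])
      pc[[v]] <- data.frame(variable = pc_vars$variable[v],
                            unit = pc_vars$unit[v], site_id = pc_cal$site_id,
                            year = pc_cal$year, month = pc_cal$month,
                            value = unname(val), stringsAsFactors = FALSE)
    }
    physchem <- do.call(rbind, pc)
    rownames(physchem) <- NULL
    list(coliform = coliform, physchem = physchem)
  })
}

#' Generate a complete synthetic study
#'
#' @param config a [synthetic_config()]
#' @return list of class `synthetic_study`: `table`, `metadata`, `tree`,
#'   `coliform`, `physchem`, `truth`, `config`
#' @export
generate_study <- function(config) {
  tree <- generate_tree(config$n_taxa, config$seed)
  cm <- generate_counts(config)
  ms <- generate_measurements(config, cm$metadata)
  validate_study(cm$table, cm$metadata, tree)
  structure(list(table = cm$table, metadata = cm$metadata, tree = tree,
                 coliform = ms$coliform, physchem = ms$physchem,
                 truth = cm$truth, config = config),
            class = "synthetic_study")
}
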