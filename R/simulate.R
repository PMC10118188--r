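#' Build a simulation configuration
#'
#' A `baci_sim_config` describes a paired-watershed (BACI) study: which
#' sites belong to which treatment group, which years are pre- and
#' post-impact, which attributes are measured at what replication, the
#' positive baseline level of every site-attribute cell, multiplicative
#' treatment-by-period effect factors, and the noise model. Values are
#' generated as
#' \deqn{v = baseline \times e^{\delta_{site}} \times f^{[post]} \times \epsilon}
#' with a site random effect \eqn{\delta_{site} \sim N(0, site\_sd)} on the
#' log scale (constant across periods) and mean-one multiplicative
#' lognormal noise \eqn{\epsilon} whose coefficient of variation is set per
#' attribute. Percent-type attributes (e.g. canopy closure) are simulated
#' on the logit scale and mapped back to `[0, 100]`, with `noise_cv`
#' interpreted as a logit-scale standard deviation and effect factors
#' applied to the odds.
#'
#' @param sites data.frame with columns `site`, `catchment`, `group`,
#'   `class` (`"headwater"` or `"downstream"`).
#' @param groups Ordered character vector of headwater treatment-group
#'   labels (factor level order for the treatment design).
#' @param pre_years,post_years Disjoint integer vectors of sampling years.
#' @param attributes Character vector of response names.
#' @param baseline Matrix `site x attribute` of positive baseline levels
#'   (rownames = sites, colnames = attributes).
#' @param effect Matrix `group x attribute` of positive post/pre
#'   multiplicative factors (rownames cover every group label in `sites`).
#' @param noise_cv Named numeric, coefficient of variation per attribute.
#' @param site_sd Standard deviation of the site random effect (log scale).
#' @param replicates Named list: attribute -> c(headwater =, downstream =)
#'   replicate counts per site-year.
#' @param percent_attributes Attributes bounded in `[0, 100]`, simulated on
#'   the logit scale.
#' @param year_effect Optional named numeric of common multiplicative year
#'   effects (default: none), to emulate climate years.
#' @param seed Integer seed; identical configs give identical tables.
#' @return An object of class `baci_sim_config`.
#' @seealso [default_trask_design()], [simulate_study()], [set_effect()]
#' @export
simulation_config <- function(sites, groups, pre_years, post_years,
                              attributes, baseline, effect, noise_cv,
                              site_sd = 0, replicates = NULL,
                              percent_attributes = character(),
                              year_effect = NULL, seed = 1L) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("site", "group", "class") %in% names(sites)))
  if (!"catchment" %in% names(sites)) sites$catchment <- NA_character_
  if (length(intersect(pre_years, post_years)) > 0L) {
    stop("pre_years and post_years must be disjoint")
  }
  baseline <- as.matrix(baseline)
  effect <- as.matrix(effect)
  if (any(!is.finite(baseline)) || any(baseline <= 0)) {
    stop("all baselines must be positive and finite")
  }
  if (any(!is.finite(effect)) || any(effect <= 0)) {
    stop("all effect factors must be positive and finite")
  }
  if (is.null(replicates)) {
    replicates <- stats::setNames(
      rep(list(c(headwater = 1, downstream = 1)), length(attributes)),
      attributes)
  }
  if (any(unlist(replicates) < 1)) stop("replicate counts must be >= 1")
  missing_grp <- setdiff(unique(sites$group), rownames(effect))
  if (length(missing_grp) > 0L) {
    stop("effect matrix lacks rows for groups: ",
         paste(missing_grp, collapse = ", "))
  }
  cfg <- list(sites = sites, groups = groups,
              pre_years = sort(as.integer(pre_years)),
              post_years = sort(as.integer(post_years)),
              attributes = attributes, baseline = baseline, effect = effect,
              noise_cv = noise_cv, site_sd = site_sd,
              replicates = replicates,
              percent_attributes = percent_attributes,
              year_effect = year_effect, seed = as.integer(seed))
  class(cfg) <- "baci_sim_config"
  cfg
}

#' Default paired-watershed study design
#'
#' Returns the layout of a 10-year Oregon Coast Range paired-watershed
#' harvest experiment: 12 headwater watersheds nested in 4 catchments
#' (3 clearcut with variable buffers, 3 clearcut with uniform buffers,
#' 1 thinned, 5 unharvested references) plus 4 downstream sites (3
#' downstream of harvest, 1 downstream reference); 5 pre-harvest years
#' (2007-2011) and 4 post-harvest years (2013-2016; no sampling in the
#' harvest year); 9 attributes spanning canopy closure, water chemistry
#' (DOC, SRP, DON, DIN, DIN:SRP molar ratio), epilithon biomass,
#' chlorophyll a and fine surface sediment. Replicate counts per
#' site-year mirror the field protocol: single chemistry grab samples,
#' 4 (headwater) / 6 (downstream) epilithon composites, 3/5 sediment
#' samples. All effect factors default to 1 (a null world); inject
#' treatment effects with [set_effect()].
#'
#' Baseline levels and noise CVs are chosen once to sit inside the ranges
#' typical of oligotrophic forested headwaters (DIN a few hundredths of a
#' mg N/L, SRP ~0.01 mg P/L, epilithon <15 g AFDM/m^2); see the methods
#' vignette for the rationale.
#'
#' @param seed Integer seed stored in the config.
#' @return A `baci_sim_config`.
#' @export
default_trask_design <- function(seed = 1L) {
  sites <- data.frame(
    site = c("UM1", "UM2", "UM3", "GS1", "GS2", "GS3",
             "PH1", "PH2", "PH3", "PH4", "RK1", "RK3",
             "UMDS", "GSDS", "PHDS", "RKDS"),
    catchment = c("UM", "UM", "UM", "GS", "GS", "GS",
                  "PH", "PH", "PH", "PH", "RK", "RK",
                  "UM", "GS", "PH", "RK"),
    group = c("reference", "clearcut variable", "clearcut variable",
              "reference", "thinned", "clearcut variable",
              "clearcut uniform", "clearcut uniform", "reference",
              "clearcut uniform", "reference", "reference",
              "downstream harvested", "downstream harvested",
              "downstream harvested", "downstream reference"),
    class = c(rep("headwater", 12), rep("downstream", 4)),
    stringsAsFactors = FALSE)
  groups <- c("clearcut variable", "clearcut uniform", "thinned",
              "reference")
  attributes <- c("canopy closure", "DOC", "SRP", "DON", "DIN", "DIN:SRP",
                  "epilithon", "chlorophyll a", "sediment")
  base_attr <- c("canopy closure" = 90, "DOC" = 0.5, "SRP" = 0.010,
                 "DON" = 0.03, "DIN" = 0.03, "DIN:SRP" = 7,
                 "epilithon" = 8, "chlorophyll a" = 7, "sediment" = 80)
  baseline <- matrix(rep(base_attr, each = nrow(sites)),
                     nrow = nrow(sites),
                     dimnames = list(sites$site, attributes))
  all_groups <- unique(sites$group)
  effect <- matrix(1, nrow = length(all_groups), ncol = length(attributes),
                   dimnames = list(all_groups, attributes))
  noise_cv <- c("canopy closure" = 0.3, "DOC" = 0.3, "SRP" = 0.4,
                "DON" = 0.4, "DIN" = 0.5, "DIN:SRP" = 0.6,
                "epilithon" = 0.4, "chlorophyll a" = 0.45,
                "sediment" = 0.5)
  chem <- c(headwater = 1, downstream = 1)
  replicates <- list(
    "canopy closure" = chem, "DOC" = chem, "SRP" = chem, "DON" = chem,
    "DIN" = chem, "DIN:SRP" = chem,
    "epilithon" = c(headwater = 4, downstream = 6),
    "chlorophyll a" = c(headwater = 4, downstream = 6),
    "sediment" = c(headwater = 3, downstream = 5))
  simulation_config(
    sites = sites, groups = groups,
    pre_years = 2007:2011, post_years = 2013:2016,
    attributes = attributes, baseline = baseline, effect = effect,
    noise_cv = noise_cv, site_sd = 0.4, replicates = replicates,
    percent_attributes = "canopy closure", seed = seed)
}

#' Inject a treatment-by-period effect into a configuration
#'
#' @param config A `baci_sim_config`.
#' @param groups Group labels to modify.
#' @param attributes Attribute names to modify.
#' @param factor Positive multiplicative post/pre effect factor.
#' @return The modified configuration.
#' @export
set_effect <- function(config, groups, attributes, factor) {
  stopifnot(inherits(config, "baci_sim_config"), factor > 0)
  config$effect[groups, attributes] <- factor
  config
}

#' Simulate a BACI observation table
#'
#' Draws one record per site x year x attribute x replicate from the
#' generative model documented in [simulation_config()]. Generation order
#' is fixed (sites in config order, attributes in config order, years
#' sorted, replicates 1..r) and all randomness flows from `config$seed`,
#' so identical configurations produce byte-identical tables.
#'
#' @param config A `baci_sim_config`.
#' @return A `baci_observations` table.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "baci_sim_config"))
  if (any(config$baseline <= 0) || any(config$effect <= 0)) {
    stop("non-positive baseline or effect factor in configuration")
  }
  sites <- config$sites
  years <- c(config$pre_years, config$post_years)
  periods <- c(rep("pre", length(config$pre_years)),
               rep("post", length(config$post_years)))

  ## layout of records, deterministic order: site, attribute, year, rep
  rec <- do.call(rbind, lapply(seq_len(nrow(sites)), function(si) {
    do.call(rbind, lapply(config$attributes, function(attr) {
      nrep <- config$replicates[[attr]][[sites$class[si]]]
      ny <- length(years)
      data.frame(
        site = sites$site[si], group = sites$group[si],
        period = rep(periods, each = nrep),
        year = rep(years, each = nrep),
        replicate = rep(seq_len(nrep), ny), attribute = attr,
        stringsAsFactors = FALSE)
    }))
  }))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  delta <- stats::rnorm(nrow(sites), 0, config$site_sd)
  names(delta) <- sites$site
  eps_z <- stats::rnorm(nrow(rec))

  yeff <- rep(1, length(years))
  names(yeff) <- as.character(years)
  if (!is.null(config$year_effect)) {
    yeff[names(config$year_effect)] <- config$year_effect
  }

  cv <- config$noise_cv[rec$attribute]
  is_pct <- rec$attribute %in% config$percent_attributes
  f <- ifelse(rec$period == "post",
              config$effect[cbind(rec$group, rec$attribute)], 1)
  b <- config$baseline[cbind(rec$site, rec$attribute)]
  d <- delta[rec$site]
  ye <- yeff[as.character(rec$year)]

  value <- numeric(nrow(rec))
  ## positive right-skewed attributes: mean-one lognormal noise
  if (any(!is_pct)) {
    sdlog <- sqrt(log(1 + cv[!is_pct]^2))
    value[!is_pct] <- b[!is_pct] * exp(d[!is_pct]) * f[!is_pct] *
      ye[!is_pct] * exp(eps_z[!is_pct] * sdlog - sdlog^2 / 2)
  }
  ## percent attributes: logit scale, effect acts on the odds
  if (any(is_pct)) {
    lg <- stats::qlogis(b[is_pct] / 100) + d[is_pct] + log(f[is_pct]) +
      log(ye[is_pct]) + eps_z[is_pct] * cv[is_pct]
    value[is_pct] <- 100 * stats::plogis(lg)
  }
  rec$value <- value
  as_baci_observations(rec)
}

#' @rdname simulation_config
#' @param path File to write/read JSON-serialized configuration.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "baci_sim_config"))
  ser <- config
  ser$baseline <- list(rownames = rownames(config$baseline),
                       colnames = colnames(config$baseline),
                       values = config$baseline)
  ser$effect <- list(rownames = rownames(config$effect),
                     colnames = colnames(config$effect),
                     values = config$effect)
  ## named vectors must go out as objects, not bare arrays
  ser$noise_cv <- as.list(config$noise_cv)
  ser$replicates <- lapply(config$replicates, as.list)
  if (!is.null(config$year_effect)) {
    ser$year_effect <- as.list(config$year_effect)
  }
  jsonlite::write_json(unclass(ser), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname simulation_config
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (fld in c("baseline", "effect")) {
    m <- as.matrix(raw[[fld]]$values)
    dimnames(m) <- list(raw[[fld]]$rownames, raw[[fld]]$colnames)
    raw[[fld]] <- m
  }
  raw$noise_cv <- unlist(raw$noise_cv)
  raw$replicates <- lapply(raw$replicates, unlist)
  if (length(raw$year_effect) == 0L) raw$year_effect <- NULL
  simulation_config(
    sites = raw$sites, groups = raw$groups, pre_years = raw$pre_years,
    post_years = raw$post_years, attributes = raw$attributes,
    baseline = raw$baseline, effect = raw$effect, noise_cv = raw$noise_cv,
    site_sd = raw$site_sd, replicates = raw$replicates,
    percent_attributes = unlist(raw$percent_attributes),
    year_effect = raw$year_effect, seed = raw$seed)
}
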