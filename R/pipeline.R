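#' Analysis configuration
#'
#' Bundles every tunable of the multi-method analysis: which factorial
#' design to fit (`"treatment-group"`, `"watershed"`, or `"downstream"`,
#' the last being the same code path with a two-level treatment factor),
#' which attributes to analyze, the significance level, resampling sizes,
#' the RMSECV selection threshold, the Box-Cox search grid, the R2CV
#' suppression floor, and the analysis unit (`"site-year"` averages
#' replicates within site-year first; `"replicate"` uses raw rows).
#'
#' @param design One of `"treatment-group"`, `"watershed"`, `"downstream"`.
#' @param attributes Attributes to analyze (NULL = all in the table).
#' @param alpha Significance level (default 0.05, used for all tests).
#' @param n_boot_bca BCa resamples (default 10000).
#' @param n_boot_wild Wild-bootstrap resamples (default 2000).
#' @param select_k_tau Relative-improvement threshold for [select_k()].
#' @param boxcox_lambdas Candidate exponents for [boxcox_search()].
#' @param boxcox_tol Minimum R2CV gain to adopt a transform.
#' @param r2cv_floor Models with R2CV <= this floor are suppressed from
#'   the significance panel (default 0).
#' @param unit `"site-year"` (default) or `"replicate"`.
#' @param groups Ordered headwater treatment-group levels.
#' @param downstream_groups Ordered downstream group levels.
#' @param seed Integer master seed for all resampling.
#' @return Object of class `baci_analysis_config`.
#' @export
analysis_config <- function(design = c("treatment-group", "watershed",
                                       "downstream"),
                            attributes = NULL, alpha = 0.05,
                            n_boot_bca = 10000, n_boot_wild = 2000,
                            select_k_tau = 0.02,
                            boxcox_lambdas = seq(-2, 3, by = 0.1),
                            boxcox_tol = 0.01, r2cv_floor = 0,
                            unit = c("site-year", "replicate"),
                            groups = c("clearcut variable",
                                       "clearcut uniform", "thinned",
                                       "reference"),
                            downstream_groups = c("downstream harvested",
                                                  "downstream reference"),
                            seed = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  cfg <- list(design = match.arg(design), attributes = attributes,
              alpha = alpha, n_boot_bca = n_boot_bca,
              n_boot_wild = n_boot_wild, select_k_tau = select_k_tau,
              boxcox_lambdas = boxcox_lambdas, boxcox_tol = boxcox_tol,
              r2cv_floor = r2cv_floor, unit = match.arg(unit),
              groups = groups, downstream_groups = downstream_groups,
              seed = as.integer(seed))
  class(cfg) <- "baci_analysis_config"
  cfg
}

## Brown-Forsythe (median-centered Levene) test of variance homogeneity
levene_test <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) return(NA_real_)
  z <- abs(values - stats::ave(values, groups, FUN = stats::median))
  fit <- stats::oneway.test(z ~ groups, var.equal = TRUE)
  unname(fit$p.value)
}

## derive a seed for a sub-analysis, kept inside 32-bit integer range
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1103 + i * 12347) %% 2147483647L)
}

#' Run the full multi-method analysis
#'
#' For each attribute: (group designs only) the per-group KS2 pre/post
#' distribution test and the BCa mean-CI overlap classification; then the
#' PLS route — Box-Cox search, LOO RMSECV selection, fit, Kramer-Sugiyama
#' DoF, Wu jackknife coefficient t-tests, wild-bootstrap HC3 intervals
#' for factor-cell predictions, and a compact letter display with pre/post
#' significance. Models whose R2CV falls at or below the suppression
#' floor are kept in the diagnostics but masked ("--") in the
#' significance panel. A model failure marks the attribute suppressed and
#' the run continues.
#'
#' @param table A `baci_observations` table (or path to one).
#' @param config A `baci_analysis_config`.
#' @return Object of class `baci_report`; see [render_tables()].
#' @export
run_analysis <- function(table, config = analysis_config()) {
  if (is.character(table)) table <- read_observations(table)
  table <- as_baci_observations(table)
  if (config$unit == "site-year") table <- site_year_means(table)

  is_group_design <- config$design %in% c("treatment-group", "downstream")
  design_groups <- if (config$design == "downstream")
    config$downstream_groups else config$groups
  tab <- table[table$group %in% design_groups, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no observations for design '",
                            config$design, "'")

  attrs <- config$attributes
  if (is.null(attrs)) attrs <- unique(tab$attribute)
  absent <- setdiff(attrs, unique(tab$attribute))
  if (length(absent) > 0L) {
    warning("attribute(s) absent from table, skipped: ",
            paste(absent, collapse = ", "))
    attrs <- setdiff(attrs, absent)
  }

  results <- list()
  log <- list()
  for (ai in seq_along(attrs)) {
    attr <- attrs[ai]
    sub <- tab[tab$attribute == attr, , drop = FALSE]
    res <- list(attribute = attr)

    ## Panels A and B: group-level nonparametric comparisons
    if (is_group_design) {
      ks_rows <- list(); bca_rows <- list()
      for (gi in seq_along(design_groups)) {
        g <- design_groups[gi]
        prev <- sub$value[sub$group == g & sub$period == "pre"]
        postv <- sub$value[sub$group == g & sub$period == "post"]
        if (length(prev) == 0L || length(postv) == 0L) next
        ks <- ks2_test(prev, postv)
        ks_rows[[g]] <- data.frame(
          group = g, D = ks$statistic_D, p_value = ks$p_value,
          n_pre = ks$n_pre, n_post = ks$n_post,
          stringsAsFactors = FALSE)
        spre <- derive_seed(config$seed, 1000 * ai + 2 * gi)
        spost <- derive_seed(config$seed, 1000 * ai + 2 * gi + 1)
        ci_pre <- bca_ci(prev, alpha = config$alpha,
                         n_boot = config$n_boot_bca, seed = spre)
        ci_post <- bca_ci(postv, alpha = config$alpha,
                          n_boot = config$n_boot_bca, seed = spost)
        bca_rows[[g]] <- data.frame(
          group = g, pre_mean = ci_pre$point_estimate,
          pre_lower = ci_pre$lower, pre_upper = ci_pre$upper,
          post_mean = ci_post$point_estimate,
          post_lower = ci_post$lower, post_upper = ci_post$upper,
          code = classify_change(ci_pre, ci_post),
          stringsAsFactors = FALSE)
      }
      res$ks2 <- if (length(ks_rows) > 0L)
        do.call(rbind, c(ks_rows, list(make.row.names = FALSE)))
      res$bca <- if (length(bca_rows) > 0L)
        do.call(rbind, c(bca_rows, list(make.row.names = FALSE)))
    }

    ## PLS route
    res$pls <- tryCatch(
      run_pls_route(sub, config, design_groups,
                    seed = derive_seed(config$seed, 500000 + ai)),
      error = function(e) list(failed = TRUE, message = conditionMessage(e),
                               suppressed = TRUE))
    log[[attr]] <- list(attribute = attr,
                        seed = derive_seed(config$seed, 500000 + ai),
                        lambda = res$pls$lambda, k = res$pls$k,
                        suppressed = isTRUE(res$pls$suppressed))
    results[[attr]] <- res
  }
  structure(list(design = config$design, config = config,
                 attributes = results, log = log),
            class = "baci_report")
}

## one attribute through the PLS pipeline
run_pls_route <- function(sub, config, design_groups, seed) {
  unit_col <- if (config$design == "watershed") "site" else "group"
  fac1_name <- if (config$design == "watershed") "Watershed" else
    "Treatment"
  lv1 <- if (config$design == "watershed") sort(unique(sub$site)) else
    design_groups
  factors <- stats::setNames(list(
    factor(sub[[unit_col]], levels = lv1),
    factor(sub$period, levels = c("pre", "post"))),
    c(fac1_name, "Period"))
  X <- build_design(factors, with_interactions = TRUE)
  y <- sub$value
  k_max <- min(ncol(X), nrow(X) - 2L)

  bc <- boxcox_search(y, X, lambdas = config$boxcox_lambdas,
                      tau = config$select_k_tau, k_max = k_max,
                      tol = config$boxcox_tol)
  if (is.na(bc$objective_value)) {
    return(list(failed = TRUE, suppressed = TRUE, lambda = bc$lambda,
                message = "no usable cross-validated model"))
  }
  yt <- boxcox_transform(y, bc$lambda, bc$shift)
  k <- bc$k
  model <- fit_pls(X, yt, k)
  dof <- pls_dof(model)
  r2cv <- bc$objective_value
  suppressed <- r2cv <= config$r2cv_floor

  jack <- wu_jackknife(X, yt, k)
  cell_key <- paste(sub[[unit_col]], sub$period, sep = "|")
  first <- !duplicated(cell_key)
  cells <- stats::setNames(which(first), cell_key[first])
  wild <- wild_bootstrap(X, yt, k, cells = cells,
                         n_resamples = config$n_boot_wild, seed = seed,
                         alpha = config$alpha, transform = bc)
  letters <- letter_display(wild)

  ## per-unit pre/post letters and significance
  units <- if (config$design == "watershed") sort(unique(sub$site)) else
    design_groups
  rows <- list()
  for (u in units) {
    pre_cell <- paste(u, "pre", sep = "|")
    post_cell <- paste(u, "post", sep = "|")
    if (!(pre_cell %in% letters$cell) || !(post_cell %in% letters$cell))
      next
    rows[[u]] <- data.frame(
      unit = u,
      pre = letters$letters[match(pre_cell, letters$cell)],
      post = letters$letters[match(post_cell, letters$cell)],
      significant = compare_cells(wild, pre_cell, post_cell),
      stringsAsFactors = FALSE)
  }
  shapiro_p <- if (length(model$residuals) >= 3 &&
                   length(model$residuals) <= 5000 &&
                   stats::sd(model$residuals) > 0) {
    unname(stats::shapiro.test(model$residuals)$p.value)
  } else NA_real_

  list(failed = FALSE, lambda = bc$lambda, shift = bc$shift, k = k,
       R2 = model$R2, R2CV = r2cv, rmsecv_curve = bc$rmsecv_curve,
       r2cv_curve = bc$r2cv_curve, dof = dof, suppressed = suppressed,
       shapiro_p = shapiro_p,
       levene_factor1_p = levene_test(model$residuals, sub[[unit_col]]),
       levene_period_p = levene_test(model$residuals, sub$period),
       jackknife = jack, wild = wild, letters = letters,
       prepost = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       model = model)
}

#' Pearson correlation screen between attributes
#'
#' Correlates site-year averages of attribute pairs within strata
#' (harvested vs. reference sites, pre vs. post period), mirroring the
#' exploratory screen relating algal responses to their putative drivers.
#' R2 is reported only where the correlation p-value is at or below
#' `alpha`; constant series are flagged.
#'
#' @param table A `baci_observations` table.
#' @param pairs List of length-2 character vectors of attribute names
#'   (default: the four driver-response pairs of the algal screen).
#' @param harvested_groups Group labels counted as harvested (default:
#'   any group other than `"reference"` among headwater labels).
#' @param alpha Significance level for reporting R2 (default 0.05).
#' @return data.frame of class `pearson_screen`: one row per pair x
#'   stratum with `r`, `R2` (NA when not significant), `p_value`, `n`.
#' @export
pearson_screen <- function(table,
                           pairs = list(
                             c("chlorophyll a", "epilithon"),
                             c("chlorophyll a", "canopy closure"),
                             c("epilithon", "DIN"),
                             c("epilithon", "DIN:SRP")),
                           harvested_groups = c("clearcut variable",
                                                "clearcut uniform",
                                                "thinned"),
                           alpha = 0.05) {
  table <- site_year_means(as_baci_observations(table))
  table$stratum_site <- ifelse(table$group %in% harvested_groups,
                               "harvested",
                               ifelse(table$group == "reference",
                                      "reference", NA))
  table <- table[!is.na(table$stratum_site), , drop = FALSE]
  out <- list()
  for (pr in pairs) {
    for (ss in c("harvested", "reference")) {
      for (pp in c("pre", "post")) {
        sub <- table[table$stratum_site == ss & table$period == pp, ]
        xa <- sub[sub$attribute == pr[1], c("site", "year", "value")]
        xb <- sub[sub$attribute == pr[2], c("site", "year", "value")]
        mg <- merge(xa, xb, by = c("site", "year"))
        n <- nrow(mg)
        if (n < 3L) next
        if (stats::sd(mg$value.x) == 0 || stats::sd(mg$value.y) == 0) {
          out[[length(out) + 1L]] <- data.frame(
            attribute_x = pr[1], attribute_y = pr[2],
            stratum = paste(ss, pp), r = NA_real_, R2 = NA_real_,
            p_value = NA_real_, n = n, flag = "constant series",
            stringsAsFactors = FALSE)
          next
        }
        ct <- stats::cor.test(mg$value.x, mg$value.y, method = "pearson")
        r <- unname(ct$estimate)
        out[[length(out) + 1L]] <- data.frame(
          attribute_x = pr[1], attribute_y = pr[2],
          stratum = paste(ss, pp), r = r,
          R2 = if (ct$p.value <= alpha) r^2 else NA_real_,
          p_value = unname(ct$p.value), n = n, flag = "",
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out) > 0L) {
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  } else {
    data.frame(attribute_x = character(), attribute_y = character(),
               stratum = character(), r = numeric(), R2 = numeric(),
               p_value = numeric(), n = integer(), flag = character(),
               stringsAsFactors = FALSE)
  }
  class(res) <- c("pearson_screen", "data.frame")
  res
}

## two-decimal p-value with round-half-up, as used in the report tables
format_p2 <- function(p) {
  ifelse(is.na(p), "", sprintf("%.2f", floor(p * 100 + 0.5) / 100))
}

#' Render report tables to files
#'
#' Writes the three report panels and the diagnostics to CSV in the
#' conventional layout: panel A (KS2 p-values, two decimals, `*` when at
#' or below alpha), panel B (change codes `increase`/`decrease`/`0`),
#' panel C (pre/post letter pairs like `AB/B`, `*` when significantly
#' different, `--` when the model was suppressed), a per-model
#' diagnostics table (lambda, k, R2, R2CV, DoF, residual-normality and
#' variance-homogeneity p-values), and a JSON file with the coefficient
#' tables and CI bounds.
#'
#' @param report A `baci_report` from [run_analysis()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
render_tables <- function(report, outdir) {
  stopifnot(inherits(report, "baci_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  attrs <- names(report$attributes)
  alpha <- report$config$alpha
  paths <- c()

  is_group_design <- report$design %in% c("treatment-group", "downstream")
  if (is_group_design) {
    groups <- if (report$design == "downstream")
      report$config$downstream_groups else report$config$groups
    pa <- matrix("", length(groups), length(attrs),
                 dimnames = list(groups, attrs))
    pb <- pa
    for (a in attrs) {
      r <- report$attributes[[a]]
      if (!is.null(r$ks2)) {
        for (i in seq_len(nrow(r$ks2))) {
          star <- if (r$ks2$p_value[i] <= alpha) "*" else ""
          pa[r$ks2$group[i], a] <- paste0(format_p2(r$ks2$p_value[i]),
                                          star)
        }
      }
      if (!is.null(r$bca)) {
        for (i in seq_len(nrow(r$bca))) {
          pb[r$bca$group[i], a] <- r$bca$code[i]
        }
      }
    }
    fa <- file.path(outdir, "panelA_ks2.csv")
    fb <- file.path(outdir, "panelB_bca.csv")
    utils::write.csv(data.frame(group = groups, pa,
                                check.names = FALSE), fa,
                     row.names = FALSE)
    utils::write.csv(data.frame(group = groups, pb,
                                check.names = FALSE), fb,
                     row.names = FALSE)
    paths <- c(paths, panelA = fa, panelB = fb)
  }

  ## panel C: pre/post letters or "--"
  units <- if (is_group_design) {
    if (report$design == "downstream") report$config$downstream_groups
    else report$config$groups
  } else {
    unique(unlist(lapply(attrs, function(a) {
      p <- report$attributes[[a]]$pls
      if (!is.null(p$prepost)) p$prepost$unit
    })))
  }
  if (length(units) > 0L) {
    pc <- matrix("--", length(units), length(attrs),
                 dimnames = list(units, attrs))
    for (a in attrs) {
      p <- report$attributes[[a]]$pls
      if (isTRUE(p$suppressed) || is.null(p$prepost)) next
      for (i in seq_len(nrow(p$prepost))) {
        star <- if (p$prepost$significant[i]) "*" else ""
        pc[p$prepost$unit[i], a] <-
          paste0(p$prepost$pre[i], "/", p$prepost$post[i], star)
      }
    }
    fc <- file.path(outdir, "panelC_pls.csv")
    utils::write.csv(data.frame(unit = units, pc, check.names = FALSE),
                     fc, row.names = FALSE)
    paths <- c(paths, panelC = fc)
  }

  diag_rows <- lapply(attrs, function(a) {
    p <- report$attributes[[a]]$pls
    data.frame(
      attribute = a,
      lambda = if (is.null(p$lambda)) NA_real_ else p$lambda,
      k = if (is.null(p$k) || is.na(p$k %||% NA)) NA_integer_ else p$k,
      R2 = p$R2 %||% NA_real_, R2CV = p$R2CV %||% NA_real_,
      DoF = p$dof %||% NA_real_,
      shapiro_p = p$shapiro_p %||% NA_real_,
      levene_factor1_p = p$levene_factor1_p %||% NA_real_,
      levene_period_p = p$levene_period_p %||% NA_real_,
      suppressed = isTRUE(p$suppressed), stringsAsFactors = FALSE)
  })
  fd <- file.path(outdir, "diagnostics.csv")
  utils::write.csv(do.call(rbind, diag_rows), fd, row.names = FALSE)
  paths <- c(paths, diagnostics = fd)

  coef_json <- lapply(attrs, function(a) {
    p <- report$attributes[[a]]$pls
    if (isTRUE(p$failed) || is.null(p$jackknife)) return(NULL)
    list(attribute = a, lambda = p$lambda, k = p$k,
         jackknife = p$jackknife$table,
         wild_coef = p$wild$coef_ci, wild_cells = p$wild$cell_ci)
  })
  fj <- file.path(outdir, "models.json")
  jsonlite::write_json(Filter(Negate(is.null), coef_json), fj,
                       auto_unbox = TRUE, digits = NA, na = "null")
  paths <- c(paths, models = fj)
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
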