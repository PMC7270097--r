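## Seasonal climatology summaries per eco-region and binomial-GLM association
## of selected-substitution carrier frequencies with environmental covariates.

SEASON_MONTHS <- list(Winter = 1:3, Spring = 4:6, Summer = 7:9, Fall = 10:12)

#' Read a monthly climatology table
#' @param path CSV with columns `region`, `variable`, `month` (1-12), `value`
#' @return data.frame
#' @export
read_climatology <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "climatology_synthetic.csv",
                        package = "mitoscan")
  }
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Seasonal climatology summaries
#'
#' Per region and variable: seasonal means and SDs (seasons Winter = JFM,
#' Spring = AMJ, Summer = JAS, Fall = OND; SD with denominator n-1) plus the
#' annual SD over the 12 monthly values, the fluctuation measure used for
#' the association models.
#'
#' @param monthly data.frame with `region`, `variable`, `month`, `value`
#' @param seasons named list of month vectors (default the JFM/AMJ/JAS/OND
#'   partition)
#' @return data.frame: region, variable, season (or "Annual"), mean, sd
#' @export
seasonal_summaries <- function(monthly, seasons = SEASON_MONTHS) {
  stopifnot(all(c("region", "variable", "month", "value") %in% names(monthly)))
  if (!setequal(unlist(seasons), 1:12)) {
    stop("seasons must partition the 12 months", call. = FALSE)
  }
  rows <- list()
  for (r in unique(monthly$region)) {
    for (v in unique(monthly$variable)) {
      sub <- monthly[monthly$region == r & monthly$variable == v, ]
      missing <- setdiff(1:12, sub$month)
      if (length(missing)) {
        stop("missing month(s) for ", r, "/", v, ": ",
             paste(month.abb[missing], collapse = ", "), call. = FALSE)
      }
      vals <- sub$value[match(1:12, sub$month)]
      for (s in names(seasons)) {
        x <- vals[seasons[[s]]]
        rows[[length(rows) + 1]] <- data.frame(
          region = r, variable = v, season = s, mean = mean(x), sd = sd(x),
          stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1]] <- data.frame(
        region = r, variable = v, season = "Annual", mean = mean(vals),
        sd = sd(vals), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("climatology_summary", "data.frame")
  out
}

#' Binomial GLM of carrier counts on covariates
#'
#' Logit-link binomial regression fitted by iteratively reweighted least
#' squares (via `stats::glm`), with Wald standard errors and p-values and a
#' separation check (diverging coefficients are flagged, never returned
#' silently).
#'
#' @param successes carrier counts per unit
#' @param totals totals per unit (>= successes)
#' @param design data.frame (or vector) of covariates; an intercept is added
#' @return list of class `glm_fit`: `coefficients` data.frame (term, estimate,
#'   se, z, p), `converged`, `separation`, `fit` (the glm object)
#' @export
fit_binomial_glm <- function(successes, totals, design) {
  if (any(totals < successes) || any(successes < 0)) {
    stop("need totals >= successes >= 0", call. = FALSE)
  }
  if (is.vector(design) && !is.list(design)) design <- data.frame(x = design)
  design <- as.data.frame(design)
  mm <- stats::model.matrix(~ ., design)
  if (qr(mm)$rank < ncol(mm)) stop("design matrix is rank-deficient", call. = FALSE)
  dat <- cbind(design, .succ = successes, .fail = totals - successes)
  form <- stats::as.formula(paste("cbind(.succ, .fail) ~",
                                  paste(names(design), collapse = " + ")))
  fit <- suppressWarnings(
    glm(form, family = binomial(), data = dat,
        control = list(epsilon = 1e-8, maxit = 100))
  )
  cf <- summary(fit)$coefficients
  separation <- !fit$converged || any(abs(cf[, "Estimate"]) > 15) ||
    any(cf[, "Std. Error"] > 100)
  out <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                    se = cf[, "Std. Error"], z = cf[, "z value"],
                    p = cf[, "Pr(>|z|)"], row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(coefficients = out, converged = fit$converged,
                 separation = separation, fit = fit),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  print(x$coefficients, digits = 4)
  if (x$separation) cat("WARNING: separation detected; estimates unreliable\n")
  invisible(x)
}

#' Carrier counts of selected replacements per region
#'
#' For each consensus-positive site, counts the individuals carrying the
#' derived (non-ancestral) residue, per region.
#'
#' @param sites integer vector of selected codon sites
#' @param aa_mat character matrix of amino acids (rows = individuals, named)
#' @param regions named character vector: region label per individual
#' @param ancestral optional named vector of ancestral residues per site;
#'   default the majority residue
#' @return list: `per_site` data.frame (site, region, carriers, total,
#'   frequency), `per_region` aggregate (region, carriers, total, frequency)
#' @export
selected_site_frequencies <- function(sites, aa_mat, regions,
                                      ancestral = NULL) {
  ids <- rownames(aa_mat)
  if (is.null(ids)) stop("aa_mat must have rownames", call. = FALSE)
  unknown <- setdiff(ids, names(regions))
  if (length(unknown)) {
    stop("individual(s) with unknown region: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  reg <- regions[ids]
  if (!length(sites)) {
    return(list(per_site = data.frame(site = integer(0), region = character(0),
                                      carriers = integer(0), total = integer(0),
                                      frequency = numeric(0)),
                per_region = data.frame(region = unique(reg), carriers = 0L,
                                        total = 0L, frequency = NA_real_)))
  }
  rows <- list()
  for (s in sites) {
    col <- aa_mat[, s]
    anc <- if (!is.null(ancestral) && !is.na(ancestral[as.character(s)])) {
      ancestral[[as.character(s)]]
    } else {
      names(sort(table(col[!is.na(col)]), decreasing = TRUE))[1]
    }
    carrier <- !is.na(col) & col != anc
    for (r in unique(reg)) {
      in_r <- reg == r & !is.na(col)
      rows[[length(rows) + 1]] <- data.frame(
        site = s, region = r, carriers = sum(carrier & in_r),
        total = sum(in_r),
        frequency = if (sum(in_r) > 0) sum(carrier & in_r) / sum(in_r) else NA,
        stringsAsFactors = FALSE)
    }
  }
  per_site <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(carriers, total) ~ region, per_site, sum)
  agg$frequency <- agg$carriers / agg$total
  list(per_site = per_site, per_region = agg)
}

#' Univariate environment-association models
#'
#' Fits one binomial GLM per environmental covariate (seasonal means and
#' annual SDs from [seasonal_summaries()]) against per-region carrier counts.
#'
#' @param per_region aggregate table from [selected_site_frequencies()]
#' @param clim_summary output of [seasonal_summaries()]
#' @param covariates optional data.frame (variable, season) rows to fit;
#'   default all seasonal means plus annual SDs
#' @return data.frame: variable, season, measure, estimate, se, z, p,
#'   separation
#' @export
env_association <- function(per_region, clim_summary, covariates = NULL) {
  if (is.null(covariates)) {
    combos <- unique(clim_summary[, c("variable", "season")])
  } else {
    combos <- covariates
  }
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    v <- combos$variable[i]; s <- combos$season[i]
    measure <- if (s == "Annual") "sd" else "mean"
    sub <- clim_summary[clim_summary$variable == v & clim_summary$season == s, ]
    x <- sub[[measure]][match(per_region$region, sub$region)]
    if (any(is.na(x))) next
    ft <- tryCatch(
      fit_binomial_glm(per_region$carriers, per_region$total, data.frame(x = x)),
      error = function(e) NULL)
    if (is.null(ft)) next
    slope <- ft$coefficients[ft$coefficients$term == "x", ]
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, season = s, measure = measure,
      estimate = slope$estimate, se = slope$se, z = slope$z, p = slope$p,
      separation = ft$separation, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
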