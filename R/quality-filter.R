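# Base-quality mixture filtering: likely false-positive variant calls sit in
# a distinct low-quality mode of the mean alternate-allele base-quality
# distribution; a 1- vs 2-component Gaussian mixture chosen by BIC separates
# them from genuine variants.

gauss_loglik <- function(x, means, vars, weights) {
  dens <- vapply(seq_along(means), function(k) {
    weights[k] * stats::dnorm(x, means[k], sqrt(vars[k]))
  }, numeric(length(x)))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(x))
  sum(log(pmax(rowSums(dens), 1e-300)))
}

fit_gauss1 <- function(x) {
  mu <- mean(x)
  v <- mean((x - mu)^2)
  list(means = mu, vars = max(v, 1e-6), weights = 1,
       loglik = gauss_loglik(x, mu, max(v, 1e-6), 1), n_iter = 0L,
       ll_trace = numeric(0))
}

# Two-component EM from one starting split; equal_var pools the variance.
em_gauss2 <- function(x, cut, equal_var, tol = 1e-8, max_iter = 500L) {
  grp <- x <= stats::quantile(x, cut)
  if (all(grp) || !any(grp)) grp <- x <= stats::median(x)
  mu <- c(mean(x[grp]), mean(x[!grp]))
  v <- c(stats::var(x[grp]), stats::var(x[!grp]))
  v[!is.finite(v) | v < 1e-6] <- 1e-6
  if (equal_var) v <- rep(mean(v), 2)
  w <- c(mean(grp), 1 - mean(grp))
  ll <- -Inf
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sqrt(v[1]))
    d2 <- w[2] * stats::dnorm(x, mu[2], sqrt(v[2]))
    tot <- pmax(d1 + d2, 1e-300)
    ll_new <- sum(log(tot))
    ll_trace <- c(ll_trace, ll_new)
    r1 <- d1 / tot
    if (is.finite(ll) && abs(ll_new - ll) <= tol * abs(ll_new)) {
      ll <- ll_new
      break
    }
    ll <- ll_new
    n1 <- sum(r1)
    n2 <- length(x) - n1
    if (n1 < 1e-8 || n2 < 1e-8) break
    mu <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / n2)
    s1 <- sum(r1 * (x - mu[1])^2)
    s2 <- sum((1 - r1) * (x - mu[2])^2)
    if (equal_var) {
      v <- rep(max((s1 + s2) / length(x), 1e-6), 2)
    } else {
      v <- pmax(c(s1 / n1, s2 / n2), 1e-6)
    }
    w <- c(n1, n2) / length(x)
  }
  resp1 <- w[1] * stats::dnorm(x, mu[1], sqrt(v[1]))
  resp2 <- w[2] * stats::dnorm(x, mu[2], sqrt(v[2]))
  list(means = mu, vars = v, weights = w, loglik = ll,
       resp1 = resp1 / pmax(resp1 + resp2, 1e-300),
       n_iter = it, ll_trace = ll_trace)
}

best_em2 <- function(x, equal_var, restarts = 10L) {
  cuts <- c(0.5, stats::runif(restarts - 1, 0.2, 0.8))
  fits <- lapply(cuts, function(cc) em_gauss2(x, cc, equal_var))
  fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
}

#' Fit a Gaussian mixture to mean alternate-allele base qualities
#'
#' Fits a single Gaussian and two-component mixtures (equal-variance and
#' free-variance) by EM with quantile-split initialisation and 10 restarts,
#' then selects among the three by BIC. When a two-component model wins, the
#' lower-mean component is flagged for discarding: its members are the
#' low-quality mode characteristic of sequencing-error artifacts.
#'
#' @param qualities Numeric vector of mean alt-allele base qualities
#'   (at least 50 values).
#' @param seed Integer seed for the EM restarts.
#' @return An object of class `tf_mixture_fit` with elements `n_components`,
#'   `means` (ascending), `variances`, `weights`, `assignments` (component
#'   index per input value, 1 = lower mean), `discard_component`, `model`
#'   (one of "1", "2E", "2V"), `model_score` (BIC of the selected model,
#'   lower is better), `bic` (all three scores), `loglik` and `ll_trace`
#'   (per-iteration EM log-likelihood of the selected two-component fit).
#' @export
fit_quality_mixture <- function(qualities, seed = 1L) {
  if (any(!is.finite(qualities))) {
    validation_error("qualities must be finite")
  }
  n <- length(qualities)
  if (n < 50) {
    insufficient_data_error(sprintf(
      "mixture fitting needs >= 50 quality values, got %d", n))
  }
  x <- as.numeric(qualities)
  with_seed(seed, {
    f1 <- fit_gauss1(x)
    f2e <- best_em2(x, equal_var = TRUE)
    f2v <- best_em2(x, equal_var = FALSE)
    bic <- c(
      `1` = -2 * f1$loglik + 2 * log(n),
      `2E` = -2 * f2e$loglik + 4 * log(n),
      `2V` = -2 * f2v$loglik + 5 * log(n)
    )
    model <- names(bic)[which.min(bic)]
    if (model == "1") {
      fit <- list(n_components = 1L, means = f1$means,
                  variances = f1$vars, weights = 1,
                  assignments = rep(1L, n), discard_component = NA_integer_,
                  model = model, model_score = unname(bic[model]), bic = bic,
                  loglik = f1$loglik, ll_trace = numeric(0))
    } else {
      f2 <- if (model == "2E") f2e else f2v
      ord <- order(f2$means)
      resp_low <- if (ord[1] == 1) f2$resp1 else 1 - f2$resp1
      fit <- list(
        n_components = 2L,
        means = f2$means[ord],
        variances = f2$vars[ord],
        weights = f2$weights[ord],
        assignments = ifelse(resp_low >= 0.5, 1L, 2L),
        discard_component = 1L,
        model = model, model_score = unname(bic[model]), bic = bic,
        loglik = f2$loglik, ll_trace = f2$ll_trace
      )
    }
    structure(fit, class = "tf_mixture_fit")
  })
}

#' @export
print.tf_mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit (%s): %d component(s)\n",
              x$model, x$n_components))
  cat("  means:", paste(sprintf("%.2f", x$means), collapse = ", "), "\n")
  if (x$n_components == 2) {
    cat(sprintf("  discard component: %d (%.1f%% of values)\n",
                x$discard_component,
                100 * mean(x$assignments == x$discard_component)))
  }
  invisible(x)
}

#' Partition variants by the fitted quality mixture
#'
#' @param sites A site table with a `mean_alt_quality` column, one row per
#'   fitted quality value.
#' @param fit A [fit_quality_mixture()] result on exactly these sites.
#' @return A list with data.frames `kept` and `discarded`; their union is the
#'   input and their intersection empty.
#' @export
filter_variants_by_quality <- function(sites, fit) {
  if (!inherits(fit, "tf_mixture_fit")) {
    validation_error("fit must come from fit_quality_mixture()")
  }
  if (nrow(sites) != length(fit$assignments)) {
    validation_error(sprintf(
      "fit has %d assignments but sites has %d rows",
      length(fit$assignments), nrow(sites)))
  }
  if (fit$n_components == 1L) {
    return(list(kept = sites, discarded = sites[0, , drop = FALSE]))
  }
  drop <- fit$assignments == fit$discard_component
  list(kept = sites[!drop, , drop = FALSE],
       discarded = sites[drop, , drop = FALSE])
}

#' Quality-filter a candidate site table
#'
#' Convenience wrapper implementing the full filtering policy: the mixture is
#' fitted on novel variants and somatic candidates only (`known = FALSE`),
#' where the low-quality mode appears; known variants are exempt and always
#' kept, mirroring the observation that the bimodality arises at novel calls
#' while known polymorphisms show a single distribution.
#'
#' @param sites Site table with `mean_alt_quality` and `known` columns.
#' @param seed Seed for the mixture fit.
#' @return List with `kept`, `discarded` and the underlying `fit` (NULL when
#'   fewer than 50 novel sites are available, in which case everything is
#'   kept with a warning).
#' @export
quality_filter <- function(sites, seed = 1L) {
  novel <- !sites$known
  if (sum(novel) < 50) {
    warning("fewer than 50 novel sites; quality filter not applied")
    return(list(kept = sites, discarded = sites[0, , drop = FALSE],
                fit = NULL))
  }
  fit <- fit_quality_mixture(sites$mean_alt_quality[novel], seed = seed)
  part <- filter_variants_by_quality(sites[novel, , drop = FALSE], fit)
  kept <- rbind(sites[!novel, , drop = FALSE], part$kept)
  kept <- kept[order(match(kept$site_id, sites$site_id)), , drop = FALSE]
  list(kept = kept, discarded = part$discarded, fit = fit)
}

#' Transition/transversion ratio of an SNV call set
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine exchanges
#' (A<->G, C<->T); everything else is a transversion. Exome call sets of good
#' quality show a ratio around 3.
#'
#' @param sites Site table with `ref`, `alt` and (optionally) `variant_type`.
#' @return The ratio transitions / transversions; `Inf` with a warning when
#'   no transversions are present.
#' @export
titv_ratio <- function(sites) {
  if (!is.null(sites$variant_type)) {
    sites <- sites[sites$variant_type == "snv", , drop = FALSE]
  }
  if (nrow(sites) == 0) validation_error("no SNV sites supplied")
  ok <- sites$ref %in% c("A", "C", "G", "T") &
    sites$alt %in% c("A", "C", "G", "T") & sites$ref != sites$alt
  if (!all(ok)) validation_error("sites must carry valid single-base ref/alt")
  ts <- (sites$ref == "A" & sites$alt == "G") |
    (sites$ref == "G" & sites$alt == "A") |
    (sites$ref == "C" & sites$alt == "T") |
    (sites$ref == "T" & sites$alt == "C")
  n_tv <- sum(!ts)
  if (n_tv == 0) {
    warning("no transversions observed; Ts/Tv ratio undefined (Inf)")
    return(Inf)
  }
  sum(ts) / n_tv
}

#' Fraction of sites flagged as known variants
#'
#' Database membership (e.g. dbSNP) is consumed as an input flag; this is a
#' QC summary, high for genuine germline call sets.
#'
#' @param sites Site table with a logical `known` column.
#' @return Fraction in `[0, 1]`.
#' @export
known_fraction <- function(sites) {
  if (nrow(sites) == 0) validation_error("empty site table")
  mean(sites$known)
}
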