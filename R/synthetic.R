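#' Generator configuration for synthetic prostate-like cohorts
#'
#' Class-conditional marginal distributions coupled by a Gaussian copula.
#' Continuous margins are log-normal (PSA) or truncated normal (age); each
#' ordinal symptom score has a per-class category-probability vector over
#' 0..5. A latent multivariate normal with the configured correlation matrix
#' is pushed through each margin's inverse CDF (continuous) or cumulative
#' probability partition (ordinal), so the sample carries both the marginal
#' shapes and the rank-correlation structure.
#'
#' @param schema A [FeatureSchema-class]; margins must be named after its
#'   features, in order.
#' @param nNegative,nPositive Class block sizes (the study cohort is 45
#'   benign / 39 carcinoma).
#' @param margins Named list, one entry per feature. Continuous entries:
#'   `list(kind = "lognormal", meanlog = c(neg, pos), sdlog = c(neg, pos))` or
#'   `list(kind = "truncnorm", mean =, sd =, lower =, upper =)` with per-class
#'   `mean`/`sd`. Ordinal entries: `list(kind = "ordinal", probs =
#'   rbind(neg, pos))`, rows summing to 1 over categories 0..5.
#' @param correlation `m x m` symmetric positive-definite latent correlation
#'   matrix with unit diagonal.
#' @param seed Default seed used by [generateCohort()].
#' @return A list of class `"GeneratorConfig"`.
#' @export
generatorConfig <- function(schema, nNegative = 45L, nPositive = 39L,
                            margins, correlation, seed = 1L) {
  m <- nFeatures(schema)
  stopifnot(nNegative >= 1, nPositive >= 1,
            identical(names(margins), featureNames(schema)),
            nrow(correlation) == m, ncol(correlation) == m)
  if (max(abs(correlation - t(correlation))) > 1e-8 ||
      max(abs(diag(correlation) - 1)) > 1e-8) {
    stop("correlation must be symmetric with unit diagonal")
  }
  if (min(eigen(correlation, symmetric = TRUE, only.values = TRUE)$values) <= 1e-8) {
    stop("correlation matrix must be positive-definite")
  }
  for (nm in names(margins)) {
    mg <- margins[[nm]]
    if (mg$kind == "ordinal") {
      stopifnot(nrow(mg$probs) == 2,
                max(abs(rowSums(mg$probs) - 1)) < 1e-8, all(mg$probs >= 0))
    }
  }
  structure(list(schema = schema, nNegative = as.integer(nNegative),
                 nPositive = as.integer(nPositive), margins = margins,
                 correlation = correlation, seed = as.integer(seed)),
            class = "GeneratorConfig")
}

# Inverse CDF of one margin for one class (1 = negative, 2 = positive).
marginQuantile <- function(margin, u, class, schema_row) {
  switch(margin$kind,
    lognormal = stats::qlnorm(u, margin$meanlog[class], margin$sdlog[class]),
    truncnorm = {
      mu <- margin$mean[class]; sd <- margin$sd[class]
      pl <- stats::pnorm(margin$lower, mu, sd)
      pu <- stats::pnorm(margin$upper, mu, sd)
      stats::qnorm(pl + u * (pu - pl), mu, sd)
    },
    ordinal = {
      cum <- cumsum(margin$probs[class, ])
      findInterval(u, cum[-length(cum)], left.open = FALSE)
    },
    stop("unknown margin kind '", margin$kind, "'"))
}

#' Generate a synthetic cohort
#'
#' Gaussian-copula sampling: per class block, latent multivariate normal draws
#' with the configured correlation are mapped through the class-conditional
#' margins. Labels are block-assigned (0 for the negative block, 1 for the
#' positive block), matching a cohort of two diagnosed groups. Fully
#' deterministic given the seed.
#'
#' @param config A [generatorConfig()] such as [defaultProstateProfile()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A [TabularDataset-class] with `nNegative + nPositive` records.
#' @export
#' @examples
#' ds <- generateCohort(defaultProstateProfile(), seed = 7)
#' table(classLabels(ds))
generateCohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "GeneratorConfig"))
  schema <- config$schema
  f <- schema@features
  m <- nFeatures(schema)
  withSeed(seed, {
    blocks <- lapply(1:2, function(class) {
      n <- if (class == 1) config$nNegative else config$nPositive
      z <- MASS::mvrnorm(n, mu = numeric(m), Sigma = config$correlation)
      u <- stats::pnorm(matrix(z, n, m))
      x <- matrix(0, n, m)
      for (j in seq_len(m)) {
        x[, j] <- marginQuantile(config$margins[[j]], u[, j], class, f[j, ])
        # keep continuous draws inside the declared domain
        if (config$margins[[j]]$kind != "ordinal") {
          x[, j] <- clamp(x[, j], f$domainMin[j], f$domainMax[j])
        }
      }
      x
    })
    tabularDataset(schema, rbind(blocks[[1]], blocks[[2]]),
                   c(rep(0L, config$nNegative), rep(1L, config$nPositive)))
  })
}

# Class-conditional marginal parameters emulating the published cohort
# descriptions: positives have higher-location, narrower PSA; IEBladder and
# Urgency shifted toward high categories in positives; the remaining symptom
# scores shifted mildly. Rows of ordinal prob matrices: negative, positive.
prostateMargins <- function() {
  mild <- rbind(c(0.24, 0.22, 0.19, 0.14, 0.12, 0.09),
                c(0.16, 0.17, 0.19, 0.17, 0.16, 0.15))
  strong <- rbind(c(0.28, 0.24, 0.18, 0.13, 0.10, 0.07),
                  c(0.07, 0.11, 0.17, 0.22, 0.23, 0.20))
  list(
    PSA = list(kind = "lognormal", meanlog = c(log(6), log(14)),
               sdlog = c(0.75, 0.38)),
    Age = list(kind = "truncnorm", mean = c(66, 70), sd = c(8, 7),
               lower = 40, upper = 95),
    IEBladder = list(kind = "ordinal", probs = strong),
    UrinateAgain = list(kind = "ordinal", probs = mild),
    Intermittency = list(kind = "ordinal", probs = mild),
    Urgency = list(kind = "ordinal", probs = strong),
    Nocturia = list(kind = "ordinal", probs = mild),
    Straining = list(kind = "ordinal", probs = mild),
    WeakUrine = list(kind = "ordinal", probs = mild))
}

# Latent correlation with the published rank ordering:
# corr(Urgency, IEBladder) > corr(PSA, Urgency) > corr(IEBladder,
# UrinateAgain) > the 0.10 symptom baseline; age nearly uncorrelated.
prostateCorrelation <- function() {
  nm <- c("PSA", "Age", "IEBladder", "UrinateAgain", "Intermittency",
          "Urgency", "Nocturia", "Straining", "WeakUrine")
  R <- matrix(0.10, 9, 9, dimnames = list(nm, nm))
  diag(R) <- 1
  R["Age", ] <- R[, "Age"] <- 0.05
  R["Age", "Age"] <- 1
  set <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set("Urgency", "IEBladder", 0.55)
  set("PSA", "Urgency", 0.35)
  set("IEBladder", "UrinateAgain", 0.25)
  set("PSA", "IEBladder", 0.20)
  R
}

#' Default prostate-like cohort profile
#'
#' A [generatorConfig()] for the nine-feature screening schema with 45
#' negative and 39 positive records, emulating the qualitative structure of
#' the clinical cohort: positives with higher-location, narrower PSA;
#' IEBladder and Urgency distributions broader and shifted upward in
#' positives; and the latent correlations ranked
#' `corr(Urgency, IEBladder) > corr(PSA, Urgency) > corr(IEBladder,
#' UrinateAgain) > 0`. The marginal parameter values are modelling choices,
#' not published statistics.
#'
#' @return A `"GeneratorConfig"`; two calls return identical configurations.
#' @export
defaultProstateProfile <- function() {
  generatorConfig(prostateSchema(), 45L, 39L, prostateMargins(),
                  prostateCorrelation(), seed = 1L)
}

#' Cohort profile with tunable class separation
#'
#' Interpolates every class-conditional margin between the pooled midpoint of
#' the default profile (`effectScale = 0`: the two classes are identically
#' distributed — a null cohort) and the default profile (`effectScale = 1`),
#' and extrapolates beyond it (`effectScale > 1` pushes the class
#' distributions apart toward near-separability). Continuous locations are
#' interpolated linearly, spreads geometrically; ordinal probability vectors
#' are exponentially tilted. The correlation structure is unchanged.
#'
#' @param effectScale Non-negative class-separation multiplier.
#' @param nNegative,nPositive Class block sizes.
#' @return A `"GeneratorConfig"`.
#' @export
#' @examples
#' nullCfg <- separabilityProfile(0)       # classes identical
#' sepCfg <- separabilityProfile(3)        # nearly separable
separabilityProfile <- function(effectScale, nNegative = 45L, nPositive = 39L) {
  if (effectScale < 0) stop("effectScale must be >= 0")
  s <- effectScale
  margins <- lapply(prostateMargins(), function(mg) {
    if (mg$kind == "ordinal") {
      mid <- colMeans(mg$probs)
      tilt <- function(p) {
        q <- mid * exp(s * (log(pmax(p, 1e-12)) - log(pmax(mid, 1e-12))))
        q / sum(q)
      }
      mg$probs <- rbind(tilt(mg$probs[1, ]), tilt(mg$probs[2, ]))
    } else {
      locField <- if (mg$kind == "lognormal") "meanlog" else "mean"
      sprField <- if (mg$kind == "lognormal") "sdlog" else "sd"
      midLoc <- mean(mg[[locField]])
      midSpr <- exp(mean(log(mg[[sprField]])))
      mg[[locField]] <- midLoc + s * (mg[[locField]] - midLoc)
      # spreads interpolate only up to the profile's own values: widening the
      # negative class beyond them would undo the location separation
      mg[[sprField]] <- midSpr * (mg[[sprField]] / midSpr)^min(s, 1)
    }
    mg
  })
  generatorConfig(prostateSchema(), nNegative, nPositive, margins,
                  prostateCorrelation(), seed = 1L)
}
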