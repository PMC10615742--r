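#' Two-sample t-test with Cohen's d
#'
#' Welch's t-test by default (Student's pooled-variance variant by flag),
#' via [stats::t.test()], with the pooled-SD Cohen's d attached as effect
#' size. Two-sided unless a direction is requested explicitly.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param variant `"welch"` (default) or `"student"`.
#' @param alternative Passed to [stats::t.test()].
#' @return A [TestResult-class].
#' @examples
#' tTestES(c(1, 2, 3), c(3, 4, 5), variant = "student")
#' @export
tTestES <- function(x, y, variant = c("welch", "student"),
                    alternative = "two.sided") {
  variant <- match.arg(variant)
  es <- cohensD(x, y)  # also validates lengths / non-degenerate variance
  tt <- t.test(x, y, var.equal = variant == "student",
               alternative = alternative)
  TestResult(sprintf("t-test (%s)", variant),
             statistic = c(t = unname(tt$statistic)),
             parameter = c(df = unname(tt$parameter)),
             pValue = tt$p.value, nPerGroup = c(length(x), length(y)),
             effect = es,
             details = list(variant = variant, alternative = alternative,
                            mean_difference = mean(x) - mean(y)))
}

#' Two-way fixed-effects ANOVA with classical eta squared
#'
#' Sequential (type-I) sum-of-squares decomposition of
#' `values ~ A * B` (or `A + B` when `interaction = FALSE`), with classical
#' eta squared (SS_effect / SS_total) for every effect. In balanced designs
#' the eta squared values over all effects plus the residual sum to 1.
#'
#' @param values Numeric response.
#' @param factorA,factorB Factors (coerced) with >= 2 levels each.
#' @param interaction Include the A:B interaction (requires every cell of
#'   the design to be non-empty).
#' @param names Labels for the two factors in the output.
#' @return Named list of [TestResult-class], one per effect.
#' @examples
#' a <- gl(2, 4); b <- gl(2, 2, 8)
#' y <- c(1, 1, 2, 2, 3, 3, 4, 4)
#' twoWayAnova(y, a, b)
#' @export
twoWayAnova <- function(values, factorA, factorB, interaction = TRUE,
                        names = c("A", "B")) {
  fa <- factor(factorA); fb <- factor(factorB)
  if (nlevels(fa) < 2L || nlevels(fb) < 2L)
    stop("both factors need at least two levels")
  if (interaction && any(table(fa, fb) == 0L))
    stop("empty design cells: the interaction term cannot be estimated")
  form <- if (interaction) values ~ fa * fb else values ~ fa + fb
  fit <- lm(form)
  at <- anova(fit)
  ssTotal <- sum(at[["Sum Sq"]])
  effects <- rownames(at)
  effects <- effects[effects != "Residuals"]
  labels <- c(fa = names[1], fb = names[2],
              `fa:fb` = paste(names, collapse = ":"))
  out <- lapply(effects, function(e) {
    eta <- if (ssTotal > 0) at[e, "Sum Sq"] / ssTotal else 0
    TestResult("two-way ANOVA",
               statistic = c(F = at[e, "F value"]),
               parameter = c(df = at[e, "Df"],
                             df_resid = at["Residuals", "Df"]),
               pValue = if (is.na(at[e, "Pr(>F)"])) 1 else at[e, "Pr(>F)"],
               nPerGroup = length(values),
               effect = EffectSize("eta_squared", min(1, eta)),
               details = list(ss = at[e, "Sum Sq"], ss_total = ssTotal))
  })
  stats::setNames(out, unname(labels[effects]))
}

#' Treatment effect in a two-group, two-period crossover design
#'
#' Repeated-measures ANOVA for an AB/BA crossover: each subject is observed
#' once per period, receiving the treatment in one period according to its
#' sequence group. The model is `value ~ treatment + period + Error(subject)`;
#' the treatment F-test comes from the within-subject stratum, and the
#' classical eta squared is SS_treatment over the total SS across strata.
#' Subjects missing a period are excluded with a warning.
#'
#' @param value Numeric response (e.g. episode counts), one per
#'   subject-period.
#' @param subject Subject identifier.
#' @param period Period factor (two levels).
#' @param treatment Treatment indicator for that subject-period.
#' @return A [TestResult-class] for the treatment effect; the period effect
#'   is in `details$period`.
#' @export
crossoverAnova <- function(value, subject, period, treatment) {
  subject <- factor(subject); period <- factor(period)
  treatment <- factor(treatment)
  keep <- stats::complete.cases(value, subject, period, treatment)
  d <- data.frame(value = value, subject = subject, period = period,
                  treatment = treatment)[keep, ]
  counts <- table(d$subject)
  full <- names(counts)[counts == nlevels(d$period)]
  if (length(full) < length(counts))
    warning(sprintf("excluding %d subject(s) missing a period",
                    length(counts) - length(full)))
  d <- d[d$subject %in% full, ]
  d$subject <- droplevels(d$subject)
  if (nlevels(d$subject) < 3L)
    stop("too few complete subjects for the crossover analysis")
  fit <- aov(value ~ treatment + period + Error(subject), data = d)
  sm <- summary(fit)
  tabs <- lapply(sm, function(s) as.data.frame(s[[1]]))
  all <- do.call(rbind, tabs)
  ssTotal <- sum(all[["Sum Sq"]])
  within <- tabs[[length(tabs)]]
  rn <- trimws(rownames(within))
  it <- match("treatment", rn)
  ip <- match("period", rn)
  if (is.na(it)) stop("treatment effect could not be estimated")
  if (ssTotal <= 1e-10 * max(1, sum(d$value^2))) {
    return(TestResult("two-way repeated-measures ANOVA (crossover)",
                      statistic = c(F = 0), pValue = 1,
                      nPerGroup = nlevels(d$subject),
                      effect = EffectSize("eta_squared", 0),
                      details = list(degenerate = TRUE)))
  }
  eta <- within[it, "Sum Sq"] / ssTotal
  periodRes <- if (!is.na(ip)) {
    list(F = within[ip, "F value"], p = within[ip, "Pr(>F)"],
         eta_squared = within[ip, "Sum Sq"] / ssTotal)
  } else NULL
  TestResult("two-way repeated-measures ANOVA (crossover)",
             statistic = c(F = within[it, "F value"]),
             parameter = c(df = within[it, "Df"],
                           df_resid = within[nrow(within), "Df"]),
             pValue = within[it, "Pr(>F)"],
             nPerGroup = nlevels(d$subject),
             effect = EffectSize("eta_squared", eta),
             details = list(period = periodRes, ss_total = ssTotal))
}

#' Kruskal-Wallis rank test across several groups
#'
#' Tie-corrected H statistic with its chi-square p-value, via
#' [stats::kruskal.test()]. Typically followed by pairwise U tests with
#' Bonferroni correction (see [mannWhitneyU()] and [adjustPvalues()]).
#'
#' @param groups List of numeric vectors (>= 2 groups).
#' @return A [TestResult-class] with statistic `H`.
#' @examples
#' kruskalWallisH(list(c(1, 2), c(3, 4), c(5, 6)))
#' @export
kruskalWallisH <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("'groups' must be a list of at least two numeric vectors")
  allv <- unlist(groups)
  if (length(unique(allv)) == 1L)
    stop("all values are tied across groups: H is undefined")
  kt <- kruskal.test(groups)
  TestResult("Kruskal-Wallis test",
             statistic = c(H = unname(kt$statistic)),
             parameter = c(df = unname(kt$parameter)),
             pValue = kt$p.value,
             nPerGroup = lengths(groups))
}
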