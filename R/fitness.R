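# Colonization-fitness analytics: CFU estimation from serial dilutions,
# limit-of-detection substitution, inoculum-corrected competitive index,
# geometric-mean summaries, paired log-scale testing, comparative-Ct
# expression.

#' CFU per gram from a serial-dilution plate count
#'
#' `cfu_per_g = colony_count * 10^dilution_exponent / plated_volume_ml *
#' homogenate_volume_ml / sample_mass_g`, where the plate received
#' `plated_volume_ml` of the `10^-dilution_exponent` dilution of a
#' homogenate of `sample_mass_g` of material in `homogenate_volume_ml`.
#'
#' @param measurements data.frame with columns `colony_count`,
#'   `dilution_exponent`, `plated_volume_ml`, `homogenate_volume_ml`,
#'   `sample_mass_g` (extra columns pass through).
#' @return the input with `cfu_per_g` and `below_lod` (zero colonies)
#'   columns added.
#' @examples
#' cfuPerGram(data.frame(colony_count = 50, dilution_exponent = 4,
#'                       plated_volume_ml = 0.1,
#'                       homogenate_volume_ml = 1,
#'                       sample_mass_g = 0.1))$cfu_per_g  # 5e7
#' @export
cfuPerGram <- function(measurements) {
  m <- as.data.frame(measurements)
  need <- c("colony_count", "dilution_exponent", "plated_volume_ml",
            "homogenate_volume_ml", "sample_mass_g")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(m$plated_volume_ml <= 0)) stop("plated_volume_ml must be > 0")
  if (any(m$sample_mass_g <= 0)) stop("sample_mass_g must be > 0")
  if (any(m$colony_count < 0)) stop("colony_count must be >= 0")
  m$cfu_per_g <- m$colony_count * 10^m$dilution_exponent /
    m$plated_volume_ml * m$homogenate_volume_ml / m$sample_mass_g
  m$below_lod <- m$colony_count == 0
  m
}

#' Substitute values below the limit of detection
#'
#' Every value below `lodValue` (including zero) is replaced by
#' `lodValue`; others pass through unchanged. Idempotent. The default of
#' 10 CFU/g matches the plating limit of detection used in the
#' competition experiments.
#'
#' @param values numeric CFU/g values.
#' @param lodValue limit of detection (> 0).
#' @return the substituted vector.
#' @export
applyLod <- function(values, lodValue = 10) {
  if (lodValue <= 0) stop("lodValue must be > 0")
  ifelse(values < lodValue, lodValue, values)
}

#' Inoculum-corrected competitive index
#'
#' `ci = (wt_out / mut_out) / (wt_in / mut_in)`: the output ratio of the
#' two strains corrected by their ratio in the inoculum. Orientation:
#' values above 1 mean a wild-type advantage (a CI of 12 reads as the
#' wild type outcompeting the mutant 12-fold). Apply [applyLod()] before
#' calling so that no count is zero.
#'
#' @param wt_out,mut_out output abundances (e.g. CFU/g, post-LOD).
#' @param wt_in,mut_in inoculum abundances.
#' @return data.frame with `ci` and `log10_ci` (vectorized).
#' @export
competitiveIndex <- function(wt_out, mut_out, wt_in, mut_in) {
  vals <- cbind(wt_out, mut_out, wt_in, mut_in)
  if (any(vals <= 0))
    stop("all counts must be positive (apply the LOD substitution first)")
  ci <- (wt_out / mut_out) / (wt_in / mut_in)
  data.frame(ci = ci, log10_ci = log10(ci))
}

#' Geometric mean with a 95 percent confidence interval
#'
#' `gm = exp(mean(log(values)))`; the interval is the t-based 95 percent
#' confidence interval of the mean on the log scale, back-transformed.
#' With one value the interval is undefined (NA bounds).
#'
#' @param values positive numbers.
#' @return `list(gm, lower, upper, n)`.
#' @export
geometricMeanCI <- function(values) {
  values <- as.numeric(values)
  if (any(values <= 0)) stop("values must be positive")
  n <- length(values)
  lv <- log(values)
  gm <- exp(mean(lv))
  if (n < 2L) return(list(gm = gm, lower = NA_real_, upper = NA_real_,
                          n = n))
  half <- stats::qt(0.975, n - 1) * stats::sd(lv) / sqrt(n)
  list(gm = gm, lower = exp(mean(lv) - half), upper = exp(mean(lv) + half),
       n = n)
}

#' Paired t-test on log-transformed data
#'
#' Standard paired Student's t-test on `log(a) - log(b)` with `n - 1`
#' degrees of freedom, two-sided. When the paired log differences are
#' constant the test is degenerate: identical vectors report `t = 0,
#' p = 1`, while a constant non-zero ratio is reported with `p = 0` and
#' the `degenerate` flag set rather than an arbitrary finite p.
#'
#' @param a,b positive numeric vectors of equal length (n >= 2).
#' @return `list(t, p.value, df, degenerate)`.
#' @export
pairedLogTTest <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("a and b must have the same length")
  if (length(a) < 2L) stop("need at least two pairs")
  if (any(a <= 0) || any(b <= 0)) stop("values must be positive")
  d <- log(a) - log(b)
  if (stats::sd(d) <= 1e-10 * max(abs(d), 1)) {
    if (mean(d) == 0)
      return(list(t = 0, p.value = 1, df = length(d) - 1L,
                  degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, p.value = 0,
                df = length(d) - 1L, degenerate = TRUE))
  }
  tt <- stats::t.test(log(a), log(b), paired = TRUE)
  list(t = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Relative expression by the comparative Ct method
#'
#' `dCt = target_ct - reference_ct`; `ddCt = dCt - mean(dCt of the
#' control group)`; fold change `2^-ddCt`. At least one control sample
#' is required.
#'
#' @param records data.frame with columns `sample_id`, `target_ct`,
#'   `reference_ct`, `group`.
#' @param controlGroup label of the baseline group (default
#'   `"control"`).
#' @return the input with `dct`, `ddct` and `fold_change` columns
#'   added.
#' @export
relativeExpressionDdct <- function(records, controlGroup = "control") {
  r <- as.data.frame(records)
  need <- c("sample_id", "target_ct", "reference_ct", "group")
  miss <- setdiff(need, names(r))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  ctrl <- r$group == controlGroup
  if (!any(ctrl)) stop("no samples in control group '", controlGroup, "'")
  r$dct <- r$target_ct - r$reference_ct
  r$ddct <- r$dct - mean(r$dct[ctrl])
  r$fold_change <- 2^(-r$ddct)
  r
}

#' Summarize per-animal competitive indices
#'
#' Builds the per-animal CI table from a long-format CFU table (one
#' `wt` and one `mut` row per animal), applying the LOD substitution
#' before the ratio, and summarizes with the geometric mean, its 95
#' percent confidence interval, and the paired log-scale t-test of
#' wild-type against mutant output abundances.
#'
#' @param cfu long-format data.frame of plating measurements (see
#'   [cfuPerGram()]) with `animal_id` and `strain_label` (`"wt"` /
#'   `"mut"`) columns.
#' @param inoculum data.frame with `strain_label` and `cfu` columns.
#' @param lodValue limit of detection passed to [applyLod()].
#' @return `list(perAnimal = data.frame(animal_id, wt_cfu_per_g,
#'   mut_cfu_per_g, ci, log10_ci), summary = data.frame(gm_ci, ci_lower,
#'   ci_upper, t, p_value, n))`.
#' @export
competitionSummary <- function(cfu, inoculum, lodValue = 10) {
  m <- cfuPerGram(cfu)
  wt <- m[m$strain_label == "wt", ]
  mut <- m[m$strain_label == "mut", ]
  ids <- sort(intersect(wt$animal_id, mut$animal_id))
  wtv <- applyLod(wt$cfu_per_g[match(ids, wt$animal_id)], lodValue)
  mutv <- applyLod(mut$cfu_per_g[match(ids, mut$animal_id)], lodValue)
  win <- inoculum$cfu[inoculum$strain_label == "wt"]
  min_ <- inoculum$cfu[inoculum$strain_label == "mut"]
  ci <- competitiveIndex(wtv, mutv, win, min_)
  per <- data.frame(animal_id = ids, wt_cfu_per_g = wtv,
                    mut_cfu_per_g = mutv, ci = ci$ci,
                    log10_ci = ci$log10_ci)
  gm <- geometricMeanCI(per$ci)
  tt <- pairedLogTTest(wtv, mutv)
  list(perAnimal = per,
       summary = data.frame(gm_ci = gm$gm, ci_lower = gm$lower,
                            ci_upper = gm$upper, t = tt$t,
                            p_value = tt$p.value, n = gm$n))
}
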