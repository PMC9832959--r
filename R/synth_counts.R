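#' Growth-model parameters for the synthetic GTme screen
#'
#' Discrete multiplicative growth: the expected count after `d` days is
#' `n0 * rate_sex^d`, with male cells growing faster than female cells by
#' default (the sex-dimorphic pattern the assay reads out). Mean nuclear area
#' rises from `size0` towards `size_plateau` as an exponential approach:
#' `size(d) = size_plateau - (size_plateau - size0) * (1 - size_rate)^d`.
#' Observed counts carry multiplicative lognormal noise of coefficient of
#' variation `count_cv` (and areas `size_cv`).
#'
#' `modulators` maps a treatment name to per-sex multiplicative effects on the
#' daily growth rate; defaults emulate methyltestosterone (MT, boosts female
#' growth) and the androgen-receptor antagonist flutamide (FLUT, attenuates
#' male growth). An optional epithelial contamination fraction adds a second
#' population with its own growth rate.
#'
#' @param rate_male,rate_female per-day multiplicative growth factors (> 0;
#'   default male 1.35 > female 1.25).
#' @param n0_range integer interval of initial cells per well (default 300-500).
#' @param size0,size_plateau initial and asymptotic mean nuclear area, pixel^2.
#' @param size_rate per-day approach rate to the plateau, in `[0, 1]`.
#' @param count_cv,size_cv coefficients of variation of observed counts/areas.
#' @param modulators named list: treatment -> c(male = f, female = f) rate
#'   multipliers.
#' @param contamination_frac fraction of seeded cells that are contaminating
#'   epithelium (0 = pure FACS-sorted population).
#' @param contamination_rate daily growth factor of the contaminating cells.
#' @param couple_size_growth when TRUE, the daily growth increment scales
#'   with the remaining distance of the nuclear size to its plateau, so
#'   proliferation slows as nuclei enlarge (the differentiation coupling);
#'   when FALSE (default) the daily rate is constant.
#' @return list of class `growth_params`.
#' @export
growth_params <- function(rate_male = 1.35, rate_female = 1.25,
                          n0_range = c(300L, 500L),
                          size0 = 60, size_plateau = 120, size_rate = 0.35,
                          count_cv = 0.08, size_cv = count_cv,
                          modulators = list(
                            MT   = c(male = 1.03, female = 1.08),
                            FLUT = c(male = 0.92, female = 1.00)),
                          contamination_frac = 0,
                          contamination_rate = 1.15,
                          couple_size_growth = FALSE) {
  stopifnot(rate_male > 0, rate_female > 0,
            length(n0_range) == 2, n0_range[1] <= n0_range[2], n0_range[1] > 0,
            size0 > 0, size_plateau >= size0,
            size_rate >= 0, size_rate <= 1,
            count_cv >= 0, size_cv >= 0,
            contamination_frac >= 0, contamination_frac < 1,
            contamination_rate > 0)
  structure(list(rate_male = rate_male, rate_female = rate_female,
                 n0_range = as.integer(round(n0_range)),
                 size0 = size0, size_plateau = size_plateau,
                 size_rate = size_rate, count_cv = count_cv, size_cv = size_cv,
                 modulators = modulators,
                 contamination_frac = contamination_frac,
                 contamination_rate = contamination_rate,
                 couple_size_growth = couple_size_growth),
            class = "growth_params")
}

sex_rate <- function(growth, sex, modulators = character()) {
  r <- if (sex == "male") growth$rate_male else growth$rate_female
  for (m in modulators) {
    eff <- growth$modulators[[m]]
    if (is.null(eff)) stop("unknown modulator: ", m)
    r <- r * unname(eff[[sex]])
  }
  r
}

# Closed-form expectations of the growth model (the zero-noise path).
expected_count <- function(growth, sex, days, n0, effect = 1,
                           modulators = character()) {
  f <- growth$contamination_frac
  r <- sex_rate(growth, sex, modulators)
  (1 - f) * n0 * cumrate(growth, r, days) * effect +
    f * n0 * growth$contamination_rate^days
}

# Cumulative growth factor over `days`. Uncoupled: r^days. Coupled: the
# daily excess over 1 shrinks with the fraction of the size trajectory
# still to run, so growth decelerates as nuclei approach the plateau.
cumrate <- function(growth, r, days) {
  if (!isTRUE(growth$couple_size_growth)) return(r^days)
  if (days == 0) return(1)
  remaining <- (growth$size_plateau - expected_size(growth, 0:(ceiling(days) - 1))) /
    (growth$size_plateau - growth$size0)
  prod(1 + (r - 1) * remaining)
}

expected_size <- function(growth, days) {
  growth$size_plateau - (growth$size_plateau - growth$size0) *
    (1 - growth$size_rate)^days
}

#' Plant compound effects for a synthetic screen
#'
#' Builds the "planted truth" effect map: each compound gets multiplicative
#' effects on the final per-well count (1.0 = null compound), a kinase-family
#' label, and an additive shift on mean nuclear area (pixel^2) so that hit
#' categories C1/C2/C3 are represented. Hypo compounds are preferentially
#' drawn into `enriched_families`, mirroring a cell-cycle-kinase-heavy hit
#' list.
#'
#' @param compound_ids character vector of compound ids.
#' @param n_hypo,n_hyper numbers of planted proliferation-inhibiting /
#'   -promoting compounds.
#' @param effect_hypo,effect_hyper multiplicative effects on final count.
#' @param families kinase-family labels to assign.
#' @param enriched_families families the hypo compounds concentrate in.
#' @param shrink_shift additive nuclear-area shift (pixel^2, negative =
#'   shrinkage) applied to shrinking compounds.
#' @param frac_hypo_shrink,frac_hyper_shrink fractions of planted hypo/hyper
#'   compounds that also shrink nuclei (C1 / C2 material; the rest are C3).
#' @param seed integer seed.
#' @return data.frame of class `effect_map`: `compound_id`, `effect_male`,
#'   `effect_female`, `family`, `size_shift_male`, `size_shift_female`.
#' @export
plant_effects <- function(compound_ids, n_hypo = 60, n_hyper = 20,
                          effect_hypo = 0.3, effect_hyper = 1.8,
                          families = c("mTOR", "PLK", "PI3K", "AuroraK",
                                       "CDK", "BcrAbl", "p38MAPK", "RAF",
                                       "ROCK", "VEGFR", "EGFR", "other"),
                          enriched_families = c("mTOR", "PLK"),
                          shrink_shift = -35,
                          frac_hypo_shrink = 0.6, frac_hyper_shrink = 0.25,
                          seed = 1) {
  n <- length(compound_ids)
  stopifnot(n_hypo + n_hyper <= n, effect_hypo > 0, effect_hyper > 0)
  with_substream(seed, "effects", {
    fam <- sample(rep_len(families, n))
    # concentrate hypo compounds in the enriched families
    w <- ifelse(fam %in% enriched_families, 6, 1)
    hypo <- sample(n, n_hypo, prob = w)
    hyper <- sample(setdiff(seq_len(n), hypo), n_hyper)
    eff <- rep(1, n)
    eff[hypo] <- effect_hypo
    eff[hyper] <- effect_hyper
    shift <- rep(0, n)
    if (n_hypo > 0) {
      sh <- hypo[seq_len(round(frac_hypo_shrink * n_hypo))]
      shift[sh] <- shrink_shift
    }
    if (n_hyper > 0) {
      sh <- hyper[seq_len(round(frac_hyper_shrink * n_hyper))]
      shift[sh] <- shrink_shift
    }
    out <- data.frame(compound_id = compound_ids,
                      effect_male = eff, effect_female = eff,
                      family = fam,
                      size_shift_male = shift, size_shift_female = shift,
                      stringsAsFactors = FALSE)
    class(out) <- c("effect_map", "data.frame")
    out
  })
}

#' Simulate per-well screen measurements
#'
#' Draws one observed (count, mean nuclear area) pair per non-empty layout
#' well at the screen endpoint: expected count `n0 * rate_sex^days *
#' effect_sex` with multiplicative lognormal noise of CV `count_cv`, floored
#' at 0 and rounded; expected mean area per the plateau model plus any
#' compound-declared size shift, with CV `size_cv`. `n0` is drawn uniformly
#' per well from `growth$n0_range`. Compounds absent from `effects` get
#' effect 1.0 (logged via message).
#'
#' @param layout a `plate_layout`.
#' @param effects an `effect_map` (or NULL: all compounds null).
#' @param growth a `growth_params`.
#' @param days screen duration in days (default 6).
#' @param seed integer seed.
#' @return data.frame of class `well_measurements`: `plate_id`, `sex`,
#'   `well`, `role`, `compound_id`, `replicate_index`, `cell_count`,
#'   `mean_nuclear_area`, `n_fields`.
#' @export
simulate_screen_counts <- function(layout, effects = NULL,
                                   growth = growth_params(), days = 6,
                                   seed = 1) {
  validate_layout(layout)
  tab <- layout[layout$role != "empty", , drop = FALSE]
  cpds <- unique(tab$compound_id[tab$role == "compound"])
  if (is.null(effects)) {
    effects <- data.frame(compound_id = cpds, effect_male = 1, effect_female = 1,
                          family = "other", size_shift_male = 0,
                          size_shift_female = 0, stringsAsFactors = FALSE)
  }
  missing <- setdiff(cpds, effects$compound_id)
  if (length(missing)) {
    message(length(missing), " compound(s) missing from effect map; using effect 1.0")
    effects <- rbind(effects,
                     data.frame(compound_id = missing, effect_male = 1,
                                effect_female = 1, family = "other",
                                size_shift_male = 0, size_shift_female = 0))
  }
  i <- match(tab$compound_id, effects$compound_id)
  eff <- ifelse(tab$sex == "male", effects$effect_male[i], effects$effect_female[i])
  eff[is.na(eff)] <- 1       # control wells
  shift <- ifelse(tab$sex == "male", effects$size_shift_male[i],
                  effects$size_shift_female[i])
  shift[is.na(shift)] <- 0

  with_substream(seed, "counts", {
    n <- nrow(tab)
    n0 <- if (growth$n0_range[1] == growth$n0_range[2]) {
      rep(growth$n0_range[1], n)
    } else {
      sample(seq(growth$n0_range[1], growth$n0_range[2]), n, replace = TRUE)
    }
    cumfac <- vapply(tab$sex, function(s)
      cumrate(growth, sex_rate(growth, s), days), numeric(1))
    f <- growth$contamination_frac
    mu <- (1 - f) * n0 * cumfac * eff +
      f * n0 * growth$contamination_rate^days
    count <- round(pmax(0, mu * lognorm_factor(n, growth$count_cv)))
    mu_size <- expected_size(growth, days) + shift
    area <- pmax(1, mu_size * lognorm_factor(n, growth$size_cv))
    out <- data.frame(plate_id = tab$plate_id, sex = tab$sex, well = tab$well,
                      role = tab$role, compound_id = tab$compound_id,
                      replicate_index = tab$replicate_index,
                      cell_count = as.integer(count),
                      mean_nuclear_area = area,
                      n_fields = NA_integer_,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    class(out) <- c("well_measurements", "data.frame")
    out
  })
}

#' Simulate a multi-day growth course
#'
#' Produces replicate (count, mean nuclear area) observations at each
#' timepoint for each condition. A condition is a sex plus a set of
#' treatment modulators whose effects compose multiplicatively on the daily
#' growth rate. Each replicate well is seeded at the midpoint of
#' `growth$n0_range` (controlled seeding density, unlike the screen's
#' per-well spread).
#'
#' @param conditions list of conditions, each `list(sex =, modulators =)`,
#'   or a character vector like `c("male", "female+MT")`.
#' @param timepoints sorted ascending vector of days.
#' @param growth a `growth_params`.
#' @param replicates replicate wells per condition per timepoint.
#' @param rate_overrides optional named list: condition label -> per-day rate
#'   multiplier (e.g. a planted siRNA knockdown effect).
#' @param seed integer seed.
#' @return data.frame of class `growth_curves`: `condition`, `sex`, `day`,
#'   `replicate`, `count`, `mean_area`.
#' @export
simulate_growth_course <- function(conditions = c("male", "female"),
                                   timepoints = 1:5,
                                   growth = growth_params(),
                                   replicates = 4,
                                   rate_overrides = NULL,
                                   seed = 1) {
  if (length(timepoints) == 0) stop("timepoints must be non-empty")
  if (is.unsorted(timepoints, strictly = TRUE)) stop("timepoints must be sorted ascending")
  if (is.character(conditions)) {
    conditions <- lapply(conditions, function(s) {
      parts <- strsplit(s, "+", fixed = TRUE)[[1]]
      list(sex = parts[1], modulators = parts[-1])
    })
  }
  n0 <- round(mean(growth$n0_range))
  with_substream(seed, "growthcourse", {
    rows <- lapply(conditions, function(cond) {
      label <- paste(c(cond$sex, cond$modulators), collapse = "+")
      r <- sex_rate(growth, cond$sex, cond$modulators %||% character())
      if (!is.null(rate_overrides[[label]])) r <- r * rate_overrides[[label]]
      do.call(rbind, lapply(timepoints, function(d) {
        mu <- n0 * cumrate(growth, r, d)
        cnt <- round(pmax(0, mu * lognorm_factor(replicates, growth$count_cv)))
        sz <- pmax(1, expected_size(growth, d) *
                     lognorm_factor(replicates, growth$size_cv))
        data.frame(condition = label, sex = cond$sex, day = d,
                   replicate = seq_len(replicates),
                   count = as.integer(cnt), mean_area = sz,
                   stringsAsFactors = FALSE)
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("growth_curves", "data.frame")
    out
  })
}
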