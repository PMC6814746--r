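#' Summarise spike calls for a single plant
#'
#' Counts accepted (uncensored) nuclear calls from cells located within a
#' reference span of the root tip, converts the count to a per-hour rate
#' over the imaging duration, and flags the plant as a responder if any
#' accepted nuclear call occurred anywhere along the root. Zone counts
#' split calls at the meristem/elongation boundary; a call exactly at the
#' boundary is meristematic (inclusive rule).
#'
#' @param calls Spike-call table for this plant (any channels; only nuclear
#'   calls are counted).
#' @param positions Data frame `cell_id`, `position_um` for this plant's
#'   cells (micrometres from the root tip).
#' @param plant_id Plant label.
#' @param duration_s Imaging duration in seconds (> 0).
#' @param genotype Optional genotype label.
#' @param n_cells_observed Number of cells tracked in the field (`NA` if
#'   unknown).
#' @param span_um Reference span from the tip within which spikes are
#'   counted for the rate (default 200).
#' @param span_mode `"filter"` (default) counts calls from cells located
#'   within `span_um`; `"rescale"` counts all calls and rescales the rate
#'   by `span_um / max(position)` (provided because the counting convention
#'   is configurable; filtering is the default).
#' @param boundary_um Meristem/elongation boundary for the zone counts
#'   (default `span_um`).
#' @return A one-row data frame (`plant_summary` schema): `plant_id`,
#'   `genotype`, `n_cells_observed`, `n_spikes_in_span`, `spikes_per_hour`,
#'   `responder`, `meristem_count`, `elongation_count`.
#' @export
summarize_plant <- function(calls, positions, plant_id,
                            duration_s, genotype = NA_character_,
                            n_cells_observed = NA_integer_,
                            span_um = 200, span_mode = c("filter", "rescale"),
                            boundary_um = span_um) {
  span_mode <- match.arg(span_mode)
  stopifnot(duration_s > 0)
  df <- as.data.frame(calls)
  df <- df[df$channel == "nuclear" & !df$censored, , drop = FALSE]
  pos <- positions$position_um[match(df$cell_id, positions$cell_id)]
  if (nrow(df) && anyNA(pos)) {
    stop(sprintf("missing position for cell(s): %s",
                 paste(unique(df$cell_id[is.na(pos)]), collapse = ", ")),
         call. = FALSE)
  }
  hours <- duration_s / 3600
  if (span_mode == "filter") {
    n_span <- sum(pos <= span_um)
    rate <- n_span / hours
  } else {
    n_span <- nrow(df)
    obs_span <- if (nrow(df)) max(pos) else span_um
    rate <- n_span / hours * span_um / max(obs_span, span_um)
  }
  data.frame(plant_id = plant_id, genotype = genotype,
             n_cells_observed = n_cells_observed,
             n_spikes_in_span = n_span,
             spikes_per_hour = rate,
             responder = nrow(df) > 0,
             meristem_count = sum(pos <= boundary_um),
             elongation_count = sum(pos > boundary_um),
             stringsAsFactors = FALSE)
}

#' Summarise every plant in a call table
#'
#' @param calls Spike-call table across plants.
#' @param plants Plant metadata: `plant_id`, `imaging_duration_s`, and
#'   optionally `genotype`, `boundary_um`, `n_cells_observed`.
#' @param positions Cell positions: `plant_id`, `cell_id`, `position_um`.
#' @inheritParams summarize_plant
#' @return A data frame with one [summarize_plant()] row per plant.
#' @export
summarize_plants <- function(calls, plants, positions, span_um = 200,
                             span_mode = c("filter", "rescale")) {
  span_mode <- match.arg(span_mode)
  df <- as.data.frame(calls)
  rows <- lapply(seq_len(nrow(plants)), function(i) {
    p <- plants[i, ]
    summarize_plant(
      calls = df[df$plant_id == p$plant_id, , drop = FALSE],
      positions = positions[positions$plant_id == p$plant_id, , drop = FALSE],
      plant_id = p$plant_id,
      duration_s = p$imaging_duration_s,
      genotype = if ("genotype" %in% names(p)) p$genotype else NA_character_,
      n_cells_observed = if ("n_cells_observed" %in% names(p))
        p$n_cells_observed else NA_integer_,
      span_um = span_um, span_mode = span_mode,
      boundary_um = if ("boundary_um" %in% names(p)) p$boundary_um else span_um)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Percentage of plants showing at least one nuclear spike
#'
#' @param summaries Plant summaries from [summarize_plants()].
#' @return Percentage in `[0, 100]`.
#' @export
responder_fraction <- function(summaries) {
  if (is.null(summaries) || nrow(summaries) == 0) {
    stop("responder_fraction needs at least one plant summary", call. = FALSE)
  }
  100 * mean(summaries$responder)
}

#' Partition spike calls between meristem and elongation zones
#'
#' A call at a position less than or equal to its plant's boundary counts
#' as meristematic; otherwise elongation. Fractions are over all accepted
#' calls and sum to 100 when any call exists.
#'
#' @param calls Spike-call table (uncensored nuclear calls are used).
#' @param positions Cell positions: `plant_id`, `cell_id`, `position_um`.
#' @param boundaries Either a single boundary in micrometres or a data
#'   frame `plant_id`, `boundary_um`.
#' @return A list with `meristem_pct`, `elongation_pct`, `n_calls`.
#' @export
partition_by_zone <- function(calls, positions, boundaries) {
  df <- as.data.frame(calls)
  df <- df[df$channel == "nuclear" & !df$censored, , drop = FALSE]
  if (nrow(df) == 0) {
    return(list(meristem_pct = NA_real_, elongation_pct = NA_real_,
                n_calls = 0L))
  }
  pos <- positions$position_um[match(paste(df$plant_id, df$cell_id),
                                     paste(positions$plant_id,
                                           positions$cell_id))]
  if (anyNA(pos)) {
    stop("every call needs a cell position for zone partitioning",
         call. = FALSE)
  }
  if (is.data.frame(boundaries)) {
    b <- boundaries$boundary_um[match(df$plant_id, boundaries$plant_id)]
    if (anyNA(b)) stop("missing zone boundary for some plant(s)",
                       call. = FALSE)
  } else {
    b <- rep(boundaries, nrow(df))
  }
  meristem <- pos <= b
  list(meristem_pct = 100 * mean(meristem),
       elongation_pct = 100 * mean(!meristem),
       n_calls = nrow(df))
}

#' Mean spike shape over accepted calls
#'
#' Arithmetic means and standard deviations of rise, fall and duration over
#' uncensored calls. Because duration is defined as rise plus fall for
#' every call, the mean duration equals the sum of the mean rise and fall.
#'
#' @param calls Spike-call table.
#' @return A list with `n`, `mean_rise_s`, `sd_rise_s`, `mean_fall_s`,
#'   `sd_fall_s`, `mean_duration_s`, `sd_duration_s`. With no uncensored
#'   call, `n = 0` and the statistics are `NA` (an empty-result marker,
#'   not an error).
#' @export
shape_means <- function(calls) {
  df <- as.data.frame(calls)
  df <- df[!df$censored, , drop = FALSE]
  if (nrow(df) == 0) {
    return(list(n = 0L, mean_rise_s = NA_real_, sd_rise_s = NA_real_,
                mean_fall_s = NA_real_, sd_fall_s = NA_real_,
                mean_duration_s = NA_real_, sd_duration_s = NA_real_))
  }
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  list(n = nrow(df),
       mean_rise_s = mean(df$rise_s), sd_rise_s = sd0(df$rise_s),
       mean_fall_s = mean(df$fall_s), sd_fall_s = sd0(df$fall_s),
       mean_duration_s = mean(df$duration_s),
       sd_duration_s = sd0(df$duration_s))
}

#' Build growth records from day-3 and day-5 root lengths
#'
#' @param df Data frame with `plant_id`, `length_day3_cm`, `length_day5_cm`.
#' @return The input with `growth_rate_cm_per_day = (day5 - day3)/2` and a
#'   `shrunk` flag for plants whose day-5 length is below day 3.
#' @export
growth_records <- function(df) {
  stopifnot(all(c("plant_id", "length_day3_cm", "length_day5_cm") %in%
                  names(df)))
  if (any(df$length_day3_cm < 0 | df$length_day5_cm < 0)) {
    stop("root lengths must be non-negative", call. = FALSE)
  }
  df$growth_rate_cm_per_day <- (df$length_day5_cm - df$length_day3_cm) / 2
  df$shrunk <- df$length_day5_cm < df$length_day3_cm
  df
}

#' Regress primary-root growth rate on spike frequency
#'
#' Ordinary least-squares line of growth rate (cm/day) against nuclear
#' spike rate (spikes/hour), using every matched plant with no outlier
#' removal.
#'
#' @param growth Growth records (see [growth_records()]).
#' @param summaries Plant summaries (see [summarize_plants()]).
#' @return A list with `slope`, `intercept`, `n`.
#' @export
correlate_growth_spiking <- function(growth, summaries) {
  m <- merge(growth[, c("plant_id", "growth_rate_cm_per_day")],
             summaries[, c("plant_id", "spikes_per_hour")],
             by = "plant_id")
  if (nrow(m) < 2L) {
    stop("need at least two plants with both measurements", call. = FALSE)
  }
  if (stats::var(m$spikes_per_hour) == 0) {
    stop("spike rates have zero variance; regression is degenerate",
         call. = FALSE)
  }
  fit <- stats::lm(growth_rate_cm_per_day ~ spikes_per_hour, data = m)
  co <- stats::coef(fit)
  list(slope = unname(co["spikes_per_hour"]),
       intercept = unname(co["(Intercept)"]),
       n = nrow(m))
}

#' Summarise a cohort by genotype
#'
#' @param summaries Plant summaries with a `genotype` column.
#' @param calls Spike-call table across the cohort (uncensored nuclear
#'   calls feed the shape means).
#' @return A data frame with one row per genotype: responder percentage,
#'   mean spike rate with standard error, mean rise/fall/duration with
#'   standard deviations, and zone percentages from the summed per-plant
#'   zone counts.
#' @export
genotype_summary <- function(summaries, calls) {
  df <- as.data.frame(calls)
  df <- df[df$channel == "nuclear" & !df$censored, , drop = FALSE]
  plant_geno <- summaries$genotype[match(df$plant_id, summaries$plant_id)]
  rows <- lapply(split(seq_len(nrow(summaries)), summaries$genotype),
                 function(idx) {
    s <- summaries[idx, , drop = FALSE]
    g <- s$genotype[1]
    sm <- shape_means(df[!is.na(plant_geno) & plant_geno == g, , drop = FALSE])
    mer <- sum(s$meristem_count)
    elo <- sum(s$elongation_count)
    data.frame(genotype = g,
               n_plants = nrow(s),
               responder_pct = responder_fraction(s),
               mean_spikes_per_hour = mean(s$spikes_per_hour),
               se_spikes_per_hour = stats::sd(s$spikes_per_hour) /
                 sqrt(nrow(s)),
               n_calls = sm$n,
               mean_rise_s = sm$mean_rise_s, sd_rise_s = sm$sd_rise_s,
               mean_fall_s = sm$mean_fall_s, sd_fall_s = sm$sd_fall_s,
               mean_duration_s = sm$mean_duration_s,
               sd_duration_s = sm$sd_duration_s,
               meristem_pct = if (mer + elo > 0)
                 100 * mer / (mer + elo) else NA_real_,
               elongation_pct = if (mer + elo > 0)
                 100 * elo / (mer + elo) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
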