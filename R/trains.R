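# Click-train grouping, qualification and per-session capping.

# Run code with a private RNG stream so seeded selection never disturbs the
# caller's random state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Click train
#'
#' @param clicks list of `ClickCandidate`, time-ordered.
#' @param session_id session identifier.
#' @param species_label optional species label.
#' @param train_id optional train identifier.
#' @return a `ClickTrain`: clicks, inter-click-interval series (`ici_series`,
#'   seconds, one fewer than clicks), qualification status and reasons.
#' @export
click_train <- function(clicks, session_id = NA_character_,
                        species_label = NA_character_,
                        train_id = NA_character_) {
  times <- vapply(clicks, `[[`, 1, "time_s")
  if (is.unsorted(times)) {
    ord <- order(times)
    clicks <- clicks[ord]; times <- times[ord]
  }
  ici <- diff(times)
  if (length(ici) && any(ici <= 0))
    stop("clicks must have strictly increasing times")
  structure(list(clicks = clicks, ici_series = ici,
                 session_id = session_id, species_label = species_label,
                 train_id = train_id,
                 qualified = NA, rejection_reasons = character(0)),
            class = "ClickTrain")
}

#' @export
print.ClickTrain <- function(x, ...) {
  cat(sprintf("ClickTrain %s: %d clicks, mean ICI %.1f ms, %s\n",
              x$train_id, length(x$clicks),
              1000 * mean(x$ici_series),
              if (isTRUE(x$qualified)) "qualified"
              else if (isFALSE(x$qualified))
                paste("rejected:", paste(x$rejection_reasons, collapse = ", "))
              else "unqualified"))
  invisible(x)
}

#' Group candidates into click trains
#'
#' A new train starts whenever the gap to the previous candidate exceeds
#' `max_gap`. The default 0.3 s is three times the 0.1 s inter-click
#' interval ceiling used in qualification, so regular trains are never
#' split while separate scanning passes are.
#'
#' @param cands time-sorted list of `ClickCandidate`.
#' @param max_gap gap (s) that separates trains (default 0.3).
#' @param session_id session identifier stamped on each train.
#' @return list of `ClickTrain`.
#' @export
group_into_trains <- function(cands, max_gap = 0.3, session_id = NA_character_) {
  if (!length(cands)) return(list())
  times <- vapply(cands, `[[`, 1, "time_s")
  if (is.unsorted(times)) stop("candidates must be time-sorted")
  grp <- cumsum(c(TRUE, diff(times) > max_gap))
  lapply(unique(grp), function(g)
    click_train(cands[grp == g], session_id = session_id,
                train_id = sprintf("%s_t%03d", session_id, g)))
}

#' Qualify a click train
#'
#' A train is retained for parameter analysis when it is a regular
#' echolocation scanning sequence recorded loud and clear:
#' \itemize{
#'   \item at least `min_clicks` clicks (default 8);
#'   \item mean inter-click interval strictly between `ici_min` and
#'     `ici_max` (defaults 10 ms and 0.1 s) — the lower bound excludes
#'     buzzes and burst pulses, the upper bound stray detections;
#'   \item train level at least `min_snr_db` (default 10 dB) above the
#'     background: RMS over 1 ms windows around the clicks against the RMS
#'     of click-free stretches of the same recording (the automatable
#'     counterpart of an editor-based "loud and clear" judgement). The
#'     level rule is skipped when no recording is supplied.
#' }
#'
#' @param train a `ClickTrain`.
#' @param rec the source `AudioRecording`, or NULL to skip the level rule.
#' @param noise optional `NoiseSpectrum`; its broadband power is the
#'   background fallback when the train span has no click-free samples.
#' @param min_clicks,ici_min,ici_max,min_snr_db rule thresholds.
#' @return the train with `qualified` and `rejection_reasons` filled in.
#' @export
qualify_train <- function(train, rec = NULL, noise = NULL,
                          min_clicks = 8, ici_min = 0.01, ici_max = 0.1,
                          min_snr_db = 10) {
  stopifnot(inherits(train, "ClickTrain"))
  reasons <- character(0)
  if (length(train$clicks) < min_clicks)
    reasons <- c(reasons, "too_few_clicks")
  mean_ici <- if (length(train$ici_series)) mean(train$ici_series) else NA_real_
  if (is.finite(mean_ici)) {
    if (mean_ici <= ici_min) reasons <- c(reasons, "ici_too_short")
    if (mean_ici >= ici_max) reasons <- c(reasons, "ici_too_long")
  }
  if (!is.null(rec)) {
    snr <- train_snr_db(train, rec, noise)
    if (!is.finite(snr) || snr < min_snr_db)
      reasons <- c(reasons, "low_snr")
  }
  train$qualified <- length(reasons) == 0
  train$rejection_reasons <- reasons
  train
}

#' Broadband level of a train above background, dB
#'
#' RMS over 1 ms windows centred on each click versus RMS of the train's
#' span with 2 ms around every click excised (falling back to the
#' whole recording's click-free samples, then to the broadband power of a
#' supplied noise spectrum).
#'
#' @inheritParams qualify_train
#' @return SNR in dB (20 log10 of the RMS ratio).
#' @export
train_snr_db <- function(train, rec, noise = NULL) {
  fs <- rec$sample_rate
  n <- length(rec$samples)
  idx <- vapply(train$clicks, `[[`, 1L, "time_index")
  half_click <- round(0.0005 * fs)
  half_guard <- round(0.002 * fs)
  click_mask <- rep(FALSE, n); guard_mask <- rep(FALSE, n)
  for (i in idx) {
    click_mask[max(1, i - half_click):min(n, i + half_click)] <- TRUE
    guard_mask[max(1, i - half_guard):min(n, i + half_guard)] <- TRUE
  }
  span <- max(1, min(idx) - round(0.05 * fs)):min(n, max(idx) + round(0.05 * fs))
  noise_idx <- span[!guard_mask[span]]
  if (!length(noise_idx)) noise_idx <- which(!guard_mask)
  click_rms <- sqrt(mean(rec$samples[click_mask]^2))
  noise_rms <- if (length(noise_idx)) {
    sqrt(mean(rec$samples[noise_idx]^2))
  } else if (!is.null(noise)) {
    sqrt(sum(noise$power))
  } else NA_real_
  if (!is.finite(noise_rms) || noise_rms <= 0) return(Inf)
  20 * log10(click_rms / noise_rms)
}

#' Session metadata record
#'
#' One row of the encounter log: species, session number, timing, position,
#' visually estimated group size, and train counts.
#'
#' @param species species name.
#' @param session_number integer session index within species.
#' @param group_size visually estimated number of individuals (>= 1).
#' @param date,start_time,latitude,longitude optional encounter metadata.
#' @param n_trains,n_selected_trains optional train counts.
#' @return a `SessionRecord` list.
#' @export
session_record <- function(species, session_number, group_size,
                           date = NA, start_time = NA,
                           latitude = NA_real_, longitude = NA_real_,
                           n_trains = NA_integer_,
                           n_selected_trains = NA_integer_) {
  stopifnot(group_size >= 1)
  if (is.finite(n_trains) && is.finite(n_selected_trains) &&
      n_selected_trains > n_trains)
    stop("n_selected_trains cannot exceed n_trains")
  structure(list(species = species, session_number = session_number,
                 date = date, start_time = start_time,
                 latitude = latitude, longitude = longitude,
                 group_size = group_size, n_trains = n_trains,
                 n_selected_trains = n_selected_trains),
            class = "SessionRecord")
}

#' Cap the trains of one session at twice the group size
#'
#' To avoid over-representing a single encounter, at most
#' `2 x group_size` qualified trains are kept per recording session;
#' when more are available a uniform random subset of that size is drawn,
#' reproducibly from `seed`. Selected trains keep their original order.
#'
#' @param trains qualified `ClickTrain`s of one session.
#' @param session the session's [session_record()].
#' @param seed integer seed for the random subset.
#' @return the selected trains (all of them when at or under the cap).
#' @export
cap_trains_per_session <- function(trains, session, seed = 1) {
  stopifnot(inherits(session, "SessionRecord"))
  limit <- 2 * session$group_size
  if (length(trains) <= limit) return(trains)
  pick <- with_local_seed(seed, sort(sample.int(length(trains), limit)))
  trains[pick]
}

#' Read session metadata from CSV
#'
#' Expects columns `species`, `session`, `group_size` and optionally
#' `date`, `start_time`, `latitude`, `longitude`, `click_trains`,
#' `selected_trains`.
#'
#' @param path CSV path.
#' @return list of `SessionRecord`.
#' @export
read_sessions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "session", "group_size")
  if (!all(need %in% names(df)))
    stop("session CSV must have columns: ", paste(need, collapse = ", "))
  get_or <- function(col, default) if (col %in% names(df)) df[[col]] else default
  lapply(seq_len(nrow(df)), function(i)
    session_record(df$species[i], df$session[i], df$group_size[i],
                   date = get_or("date", NA)[i],
                   start_time = get_or("start_time", NA)[i],
                   latitude = get_or("latitude", NA_real_)[i],
                   longitude = get_or("longitude", NA_real_)[i],
                   n_trains = get_or("click_trains", NA_integer_)[i],
                   n_selected_trains = get_or("selected_trains", NA_integer_)[i]))
}

#' Summarize trains as a data frame
#'
#' @param trains list of `ClickTrain`.
#' @return data frame with `train_id`, `session_id`, `n_clicks`,
#'   `mean_ici_ms`, `qualified`, `rejection_reasons`.
#' @export
trains_table <- function(trains) {
  data.frame(
    train_id = vapply(trains, function(t) as.character(t$train_id), ""),
    session_id = vapply(trains, function(t) as.character(t$session_id), ""),
    n_clicks = vapply(trains, function(t) length(t$clicks), 1L),
    mean_ici_ms = vapply(trains, function(t)
      if (length(t$ici_series)) 1000 * mean(t$ici_series) else NA_real_, 1),
    qualified = vapply(trains, function(t) isTRUE(t$qualified), TRUE),
    rejection_reasons = vapply(trains, function(t)
      paste(t$rejection_reasons, collapse = ";"), ""),
    stringsAsFactors = FALSE)
}
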