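# Cross-dataset direction concordance: do events regulated in one
# analysis (e.g. a knockdown cell line) move the same way in another
# (e.g. driver-high vs driver-low tumors)?

#' Compare RASE directions between two analyses
#'
#' Events are matched across datasets by their (gene, type, alternative
#' region) coordinates. Before comparison the sign conventions are
#' harmonized: set `invert_a`/`invert_b` for a dataset in which condition
#' b is the *low*-driver side (e.g. a knockdown run where condition b is
#' the knockdown), so that "up" uniformly means a higher AS ratio with
#' higher driver expression.
#'
#' Per matched event the dataset-b direction is one of `up`, `down`,
#' `flat` (present but with an AS-ratio change at or below
#' `flat_threshold`) or `absent` (untestable or missing in b); agreement
#' is `same`/`opposite` when both directions are up/down, otherwise
#' `untestable`.
#'
#' @param rases_a,rases_b Outputs of [call_rases()] for the two analyses.
#' @param events_a,events_b The corresponding event tables (for the
#'   matching keys).
#' @param invert_a,invert_b Flip the direction sign of a dataset before
#'   comparison. Default `FALSE`.
#' @param flat_threshold Dataset-b AS-ratio changes at or below this are
#'   classed `flat` rather than given a direction. Default 0.05.
#' @param restrict_to_called_a Compare only events called regulated in
#'   dataset a (the validation-set framing). Default TRUE.
#' @return List with `n_same`, `n_opposite`, `n_untestable`, and a
#'   per-event `records` data.frame (`event_key`, `direction_a`,
#'   `direction_b`, `agreement`).
#' @export
compare_directions <- function(rases_a, rases_b, events_a, events_b,
                               invert_a = FALSE, invert_b = FALSE,
                               flat_threshold = 0.05,
                               restrict_to_called_a = TRUE) {
  key_a <- event_match_keys(events_a)
  key_b <- event_match_keys(events_b)
  if (anyDuplicated(key_a)) stop("duplicate event keys in dataset a")
  if (anyDuplicated(key_b)) stop("duplicate event keys in dataset b")
  ka <- key_a[match(rases_a$event_id, events_a$event_id)]
  kb <- key_b[match(rases_b$event_id, events_b$event_id)]

  flip <- function(d, inv) {
    if (!inv) return(d)
    ifelse(d == "up", "down", ifelse(d == "down", "up", d))
  }
  dir_a <- flip(rases_a$direction, invert_a)
  dir_b_all <- flip(rases_b$direction, invert_b)

  sel <- if (restrict_to_called_a) rases_a$is_rase else rases_a$testable
  sel[is.na(sel)] <- FALSE
  records <- data.frame(event_key = ka[sel],
                        direction_a = dir_a[sel],
                        stringsAsFactors = FALSE)
  hit <- match(records$event_key, kb)
  db <- rep(NA_character_, nrow(records))
  present <- !is.na(hit)
  if (any(present)) {
    hb <- hit[present]
    testable_b <- rases_b$testable[hb] & !is.na(rases_b$rase_ratio[hb])
    db[present] <- ifelse(!testable_b, "absent",
                          ifelse(rases_b$rase_ratio[hb] <= flat_threshold,
                                 "flat", dir_b_all[hb]))
    db[present][is.na(db[present])] <- "flat"  # zero change, no direction
  }
  db[!present] <- "absent"
  records$direction_b <- db
  records$agreement <- ifelse(
    records$direction_b %in% c("up", "down") & !is.na(records$direction_a),
    ifelse(records$direction_a == records$direction_b, "same", "opposite"),
    "untestable")
  list(n_same = sum(records$agreement == "same"),
       n_opposite = sum(records$agreement == "opposite"),
       n_untestable = sum(records$agreement == "untestable"),
       records = records)
}

# Matching key: gene + type + alternative-region coordinates.
event_match_keys <- function(events) {
  sprintf("%s|%s|%s:%d-%d:%s", events$gene_id, events$event_type,
          events$chrom, events$alt_start, events$alt_end, events$strand)
}
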