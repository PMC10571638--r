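#' @keywords internal
"_PACKAGE"

## Internal constants shared across modules

.corners <- c("reward", "water", "inactive")
.sides <- c("left", "right", "none")
## canonical within-timestamp ordering of event kinds
.kinds <- c("visit_start", "nosepoke", "lick", "visit_end")
.phases <- c(
  "adaptation", "initiation_4", "initiation_8", "initiation_12",
  "free_access", "motivation", "extinction", "cue_relapse",
  "alcohol_relapse", "persistence"
)

.behaviors <- c("M", "E", "CR", "AR", "P")

.SECONDS_PER_DAY <- 86400

#' Default volume of a single lick
#'
#' Cohort-wide lick-volume constant, in microlitres, used to convert lick
#' counts to consumed volume when no calibration measurement is supplied.
#' @format A length-one numeric (microlitres per lick).
#' @export
DEFAULT_LICK_VOLUME_UL <- 1.94

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_audcage <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "audcage_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

## integer key identifying (animal, visit_seq) pairs; visit_seq < 1e7 assumed
visit_key <- function(animal_idx, visit_seq) {
  as.numeric(animal_idx) * 1e7 + as.numeric(visit_seq)
}
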