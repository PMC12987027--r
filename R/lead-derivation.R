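# The 12 standard leads from 10 electrodes.  Limb leads are potential
# differences between RA, LA, LL; augmented leads are referenced to the mean
# of the other two limbs; chest leads V1..V6 are referenced to the Wilson
# central terminal WCT = (RA + LA + LL)/3.  RL is the driven reference and
# enters no formula.

LEADS_12 <- c("I", "II", "III", "aVR", "aVL", "aVF",
              "V1", "V2", "V3", "V4", "V5", "V6")
LEADS_8 <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")

ELECTRODE_COLS <- c("RA", "LA", "LL", paste0("V", 1:6, "e"))

check_electrodes <- function(electrodes) {
  if (!is.data.frame(electrodes))
    stop("`electrodes` must be a data frame of potential series", call. = FALSE)
  missing <- setdiff(ELECTRODE_COLS, names(electrodes))
  if (length(missing))
    stop("missing electrode column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  lens <- lengths(electrodes[ELECTRODE_COLS])
  if (length(unique(lens)) != 1L)
    stop("electrode series must all have the same length", call. = FALSE)
  invisible(electrodes)
}

#' Wilson central terminal
#'
#' The sample-wise mean of the right-arm, left-arm and left-leg electrode
#' potentials, used as the reference for the unipolar chest leads.
#'
#' @param electrodes data frame with columns `RA`, `LA`, `LL` (and, for the
#'   full derivation, `V1e`..`V6e`), each a potential series in microvolts.
#' @return numeric vector, `(RA + LA + LL) / 3`.
#' @export
#' @examples
#' wilson_central_terminal(data.frame(RA = 3, LA = 0, LL = 0,
#'   V1e = 0, V2e = 0, V3e = 0, V4e = 0, V5e = 0, V6e = 0))
wilson_central_terminal <- function(electrodes) {
  if (!all(c("RA", "LA", "LL") %in% names(electrodes)))
    stop("`electrodes` must contain RA, LA, LL", call. = FALSE)
  with(electrodes, {
    if (length(RA) != length(LA) || length(LA) != length(LL))
      stop("RA, LA, LL must have equal length", call. = FALSE)
    (RA + LA + LL) / 3
  })
}

#' Derive the 12 standard leads from electrode potentials
#'
#' Classical Einthoven/Goldberger/Wilson combinations: `I = LA - RA`,
#' `II = LL - RA`, `III = LL - LA`, `aVR = RA - (LA + LL)/2`,
#' `aVL = LA - (RA + LL)/2`, `aVF = LL - (RA + LA)/2`, and
#' `Vi = Vie - WCT`.
#'
#' @inheritParams wilson_central_terminal
#' @param fs sampling rate in Hz.
#' @param posture optional posture label carried on the recording.
#' @return a 12-channel [lead_recording()] in the fixed order I, II, III,
#'   aVR, aVL, aVF, V1--V6.
#' @export
derive_12_from_electrodes <- function(electrodes, fs = 500, posture = NA_character_) {
  check_electrodes(electrodes)
  e <- electrodes
  wct <- wilson_central_terminal(e)
  out <- cbind(
    I = e$LA - e$RA,
    II = e$LL - e$RA,
    III = e$LL - e$LA,
    aVR = e$RA - (e$LA + e$LL) / 2,
    aVL = e$LA - (e$RA + e$LL) / 2,
    aVF = e$LL - (e$RA + e$LA) / 2,
    V1 = e$V1e - wct, V2 = e$V2e - wct, V3 = e$V3e - wct,
    V4 = e$V4e - wct, V5 = e$V5e - wct, V6 = e$V6e - wct
  )
  lead_recording(out, fs = fs, posture = posture)
}

#' Derive the 12 leads from the 8 transmitted channels
#'
#' The device transmits I, II and the (already WCT-referenced) chest leads.
#' The remaining limb leads are algebraic consequences: `III = II - I`,
#' `aVR = -(I + II)/2`, `aVL = I - II/2`, `aVF = II - I/2`.  The validity
#' mask of a derived lead is the conjunction of its source channels' masks.
#'
#' @param rec an 8-channel [lead_recording()] with channels I, II, V1--V6.
#' @return a 12-channel [lead_recording()].
#' @export
derive_12_from_channels <- function(rec) {
  stopifnot(inherits(rec, "lead_recording"))
  missing <- setdiff(LEADS_8, lead_names(rec))
  if (length(missing))
    stop("missing source channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  s <- rec$signals
  v <- rec$valid
  out <- cbind(
    I = s[, "I"], II = s[, "II"],
    III = s[, "II"] - s[, "I"],
    aVR = -(s[, "I"] + s[, "II"]) / 2,
    aVL = s[, "I"] - s[, "II"] / 2,
    aVF = s[, "II"] - s[, "I"] / 2,
    s[, paste0("V", 1:6), drop = FALSE]
  )
  both <- v[, "I"] & v[, "II"]
  mask <- cbind(
    I = v[, "I"], II = v[, "II"],
    III = both, aVR = both, aVL = both, aVF = both,
    v[, paste0("V", 1:6), drop = FALSE]
  )
  lead_recording(out[, LEADS_12, drop = FALSE], fs = rec$fs,
                 valid = mask[, LEADS_12, drop = FALSE],
                 posture = rec$posture)
}

#' Project electrode potentials onto the transmitted channel set
#'
#' Convenience used to emulate the device path: computes I, II and V1--V6
#' exactly as the hardware front end would (chest electrodes referenced to
#' the WCT) and returns the 8-channel recording.
#'
#' @inheritParams derive_12_from_electrodes
#' @return an 8-channel [lead_recording()].
#' @export
electrodes_to_channels <- function(electrodes, fs = 500, posture = NA_character_) {
  full <- derive_12_from_electrodes(electrodes, fs = fs, posture = posture)
  lead_recording(full$signals[, LEADS_8, drop = FALSE], fs = fs,
                 valid = full$valid[, LEADS_8, drop = FALSE],
                 posture = posture)
}
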