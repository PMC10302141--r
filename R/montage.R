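#' Electrode montage for the four isometric maneuvers
#'
#' Maps each maneuver to its agonist and antagonist electrode sets on the
#' dominant-side upper arm (five electrodes: #1-#3 over biceps brachii,
#' #4-#5 over triceps brachii) and thigh (six electrodes: #1-#3 over rectus
#' femoris, #4-#6 over biceps femoris). During elbow flexion (EF) the biceps
#' electrodes are agonists and the triceps electrodes antagonists; the roles
#' swap for elbow extension (EE), and analogously at the knee (KE: rectus
#' femoris agonist; KF: biceps femoris agonist).
#'
#' @return A named list with one entry per maneuver, each holding `segment`
#'   (`"arm"` or `"thigh"`), `agonist` and `antagonist` electrode id vectors.
#' @examples
#' study_montage()$EF
#' @export
study_montage <- function() {
  list(
    EF = list(segment = "arm",   agonist = c("1", "2", "3"), antagonist = c("4", "5")),
    EE = list(segment = "arm",   agonist = c("4", "5"),      antagonist = c("1", "2", "3")),
    KE = list(segment = "thigh", agonist = c("1", "2", "3"), antagonist = c("4", "5", "6")),
    KF = list(segment = "thigh", agonist = c("4", "5", "6"), antagonist = c("1", "2", "3"))
  )
}

check_montage <- function(montage) {
  stopifnot(is.list(montage), all(MANEUVERS %in% names(montage)))
  for (m in MANEUVERS) {
    mo <- montage[[m]]
    if (length(intersect(mo$agonist, mo$antagonist)) > 0)
      stop("montage for ", m, ": agonist and antagonist sets overlap")
  }
  invisible(montage)
}
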