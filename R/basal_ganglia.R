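# The 9-node Boolean model of the basal ganglia-thalamocortical circuit.
#
# Nine brain areas, ordered so that SC is cell 1 (the most significant bit of
# the state code): SC, Thalamus, RTN, GPi/SNr, STN, GPe, Str-D2, Str-D1,
# Cerebral Cortex.  One input unit (the ascending sensory pathway) projects
# to SC and Thalamus with weight 1.  Excitatory connections are positive,
# inhibitory negative; the published adjacency matrix is reproduced verbatim
# below (rows are sources, columns targets).

.bg_cells <- c("SC", "Thalamus", "RTN", "GPi/SNr", "STN", "GPe",
               "Str-D2", "Str-D1", "CCortex")

.bg_weight_table <- function() {
  W <- matrix("0", 9, 9, dimnames = list(.bg_cells, .bg_cells))
  W["SC", "Thalamus"] <- "1"
  W["Thalamus", c("RTN", "STN", "GPe", "Str-D2", "Str-D1", "CCortex")] <- "1"
  W["RTN", "Thalamus"] <- "-1"
  W["GPi/SNr", c("SC", "Thalamus", "RTN")] <- "-1"
  W["STN", c("GPi/SNr", "GPe", "CCortex")] <- "2"
  W["GPe", c("RTN", "GPi/SNr", "STN", "Str-D2", "Str-D1")] <- "-1/2"
  W["Str-D2", "GPe"] <- "-1"
  W["Str-D1", c("GPi/SNr", "GPe")] <- "-1/2"
  W["CCortex", c("SC", "Thalamus", "RTN", "STN", "Str-D2", "Str-D1")] <- "1/2"
  W
}

#' The basal ganglia-thalamocortical network model
#'
#' Builds the 9-cell Boolean network of the basal ganglia-thalamocortical
#' circuit: published cell-to-cell weights, one input unit wired to SC and
#' Thalamus with weight 1, uniform threshold 1.
#'
#' The published model prints neither background activities nor the threshold
#' comparison; those two parameters are calibrated (see [bg_calibrate()])
#' against the published reference trajectory and state census.  The default
#' arguments are the calibrated values - the unique configuration on the
#' calibration grid reproducing both - namely comparison `"at_least"` and a
#' background of +1/2 on Thalamus (all other cells 0).  These values are
#' inferred, not printed in the original description of the circuit.
#'
#' @param background named rational vector of per-cell backgrounds; names must
#'   be cell names, missing cells get 0.
#' @param comparison threshold comparison mode.
#' @param output_layer optional output layer (the circuit is normally analysed
#'   without one, via an explicit attractor typing).
#' @return A [boolean_network()] with 9 cells and 1 input unit.
#' @examples
#' net <- basal_ganglia_network()
#' net$n_cells
#' @export
basal_ganglia_network <- function(background = c(Thalamus = "1/2"),
                                  comparison = "at_least",
                                  output_layer = character()) {
  bg <- rep("0", 9)
  if (length(background)) {
    if (is.null(names(background)))
      stop("background must be a named vector", call. = FALSE)
    unknown <- setdiff(names(background), .bg_cells)
    if (length(unknown)) stop("unknown cells: ", paste(unknown, collapse = ", "), call. = FALSE)
    bg[match(names(background), .bg_cells)] <- as.character(background)
  }
  Win <- matrix("0", 1, 9, dimnames = list("IN", .bg_cells))
  Win["IN", c("SC", "Thalamus")] <- "1"
  boolean_network(.bg_weight_table(), input_weights = Win, background = bg,
                  thresholds = "1", comparison = comparison,
                  output_layer = output_layer)
}

#' Cell roles used by the neurobiological typing rule
#'
#' Positions (1-based indices into the firing vector) of the three areas the
#' meaningful/spurious rule inspects.
#'
#' @return named integer vector with elements `SC`, `Thalamus`, `GPi_SNr`.
#' @export
bg_roles <- function() c(SC = 1L, Thalamus = 2L, GPi_SNr = 4L)

#' Published reference trajectory of the circuit
#'
#' The closed walk through the state graph used to calibrate the model's
#' unprinted parameters, together with an input sequence that realises it
#' from the all-quiet state (found by forward simulation).
#'
#' @return list with `states` (12 state codes, first = last = 0) and `inputs`
#'   (the 11 input bits driving each transition under the calibrated model).
#' @export
bg_reference_walk <- function() {
  list(states = c(0L, 0L, 384L, 223L, 511L, 191L, 63L, 33L, 128L, 95L, 33L, 0L),
       inputs = c(0L, 1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 0L, 0L))
}

# Published per-state cycle census of the circuit's strongly connected
# component (the reference table the calibration is scored against).
.bg_reference_census <- function() {
  data.frame(
    state = c(0L, 31L, 33L, 63L, 95L, 127L, 128L, 159L, 161L, 191L, 223L,
              255L, 384L, 417L, 479L, 511L),
    n_cycles = c(68L, 47L, 87L, 93L, 39L, 21L, 63L, 77L, 72L, 52L, 43L, 53L,
                 67L, 35L, 48L, 84L),
    n_constitutive = c(24L, 20L, 24L, 21L, 21L, 17L, 24L, 22L, 20L, 19L, 21L,
                       17L, 24L, 20L, 16L, 21L))
}
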