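# Muscle selector: routes one signed control action to the agonist or
# antagonist channel of a degree of freedom. A positive action stimulates the
# agonist (increases the angle); a negative action the antagonist. The two
# channels of a pair are never commanded simultaneously (no co-contraction).

#' Agonist/antagonist channel pair for one degree of freedom
#'
#' Default ankle mapping (configurable): sagittal pair = tibialis anterior
#' (dorsiflexion, agonist) vs gastrocnemius (plantar flexion); frontal pair =
#' flexor hallucis longus (inversion, agonist) vs peroneus longus/brevis
#' (eversion). No deadzone pre-compensation is applied here: the motor
#' threshold is a plant property the controller has to fight, not something
#' the selector offsets.
#'
#' @param agonist_channel Channel id whose stimulation increases the angle.
#' @param antagonist_channel Channel id whose stimulation decreases the angle;
#'   must differ from `agonist_channel`.
#' @param dof `"sagittal"` or `"frontal"`.
#' @return An object of class `channel_pair`.
#' @export
channel_pair <- function(agonist_channel, antagonist_channel,
                         dof = c("sagittal", "frontal")) {
  dof <- match.arg(dof)
  stopifnot(agonist_channel != antagonist_channel)
  structure(list(agonist_channel = as.integer(agonist_channel),
                 antagonist_channel = as.integer(antagonist_channel),
                 dof = dof),
            class = "channel_pair")
}

#' Route a signed control action to stimulation channels
#'
#' @param u Signed control action in duty%% (typically a PID output), or the
#'   `action` list returned by [pid_step()].
#' @param pair A [channel_pair()].
#' @return An object of class `channel_command`: a named numeric vector of
#'   non-negative duties (percent), names are the channel ids. Exactly one of
#'   the pair is nonzero unless `u == 0`; the commanded magnitude equals
#'   `|u|`.
#' @examples
#' pair <- channel_pair(1, 2, "sagittal")
#' route_action(8, pair)    # agonist at 8%
#' route_action(-12, pair)  # antagonist at 12%
#' @export
route_action <- function(u, pair) {
  if (is.list(u)) u <- u$u
  stopifnot(is.numeric(u), length(u) == 1, is.finite(u),
            inherits(pair, "channel_pair"))
  duties <- c(max(u, 0), max(-u, 0))
  names(duties) <- c(pair$agonist_channel, pair$antagonist_channel)
  structure(duties, class = "channel_command")
}

#' Merge channel commands from several degree-of-freedom pairs
#'
#' @param ... `channel_command` objects over disjoint channel sets.
#' @return A single named duty vector covering all channels.
#' @export
merge_commands <- function(...) {
  cmds <- list(...)
  out <- unlist(lapply(cmds, unclass))
  if (anyDuplicated(names(out)))
    stop("channel commanded by more than one pair", call. = FALSE)
  structure(out, class = "channel_command")
}
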