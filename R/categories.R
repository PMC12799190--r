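#' Canonical visual category taxonomy
#'
#' The eight visual categories a fixation can land on during free exploration
#' of the virtual city: background elements, ordinary buildings, task-relevant
#' residential and public buildings, global landmarks, and the three agent
#' conditions (acontextual, congruent, incongruent).
#'
#' @return Character vector of length 8, in canonical order.
#' @export
gaze_categories <- function() {
  c("background", "building", "task_residential", "task_public",
    "landmark", "agent_acontextual", "agent_congruent", "agent_incongruent")
}

#' Agent condition labels
#'
#' @return Character vector of the three agent conditions.
#' @export
agent_types <- function() {
  c("acontextual", "congruent", "incongruent")
}

#' Categories that denote fixations on a human agent
#' @return Character vector of the three agent categories.
#' @export
agent_categories <- function() {
  c("agent_acontextual", "agent_congruent", "agent_incongruent")
}

# internal: map agent category label -> condition label
.category_to_condition <- function(category) {
  sub("^agent_", "", category)
}
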