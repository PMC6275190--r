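#' The command grammar
#'
#' A closed, regular set of commands over a small lexicon.  `move` and `go`
#' are synonyms.  The sentence set comprises the four primitives
#' (`turn left/right`, `move forward/backward`), `stop`, the compounds
#' (`move left/right`, `go left/right`: turn, then one step forward),
#' `turn toward the <kind>`, `explore`, `move to the box`, and
#' `move to the room before the room with the <color> <kind>` for all four
#' colour-kind combinations (plus their `go` variants).  Every sentence maps
#' to a goal label and optional colour/kind parameters.
#'
#' @return a `command_grammar` list with elements `lexicon`, `states`,
#'   `transition` (a total transition table with explicit reject sink),
#'   `start`, `accepts` (accept-state -> goal mapping) and `sentences`
#'   (the enumerated sentence strings).
#' @export
command_grammar <- function() {
  lexicon <- c("move", "turn", "go", "to", "the", "room", "before", "with",
               "left", "right", "forward", "backward", "stop", "explore",
               "toward", "pyramid", "stalactite", "red", "blue", "box")
  edges <- list(
    c("root", "turn", "q_turn"), c("root", "move", "q_move"),
    c("root", "go", "q_move"),
    c("root", "stop", "A_stop"), c("root", "explore", "A_explore"),
    c("q_turn", "left", "A_turn_left"), c("q_turn", "right", "A_turn_right"),
    c("q_turn", "toward", "q_toward"), c("q_toward", "the", "q_toward_the"),
    c("q_toward_the", "pyramid", "A_toward_pyramid"),
    c("q_toward_the", "stalactite", "A_toward_stalactite"),
    c("q_move", "forward", "A_move_forward"),
    c("q_move", "backward", "A_move_backward"),
    c("q_move", "left", "A_move_left"), c("q_move", "right", "A_move_right"),
    c("q_move", "to", "q_to"), c("q_to", "the", "q_to_the"),
    c("q_to_the", "box", "A_box"), c("q_to_the", "room", "q_room"),
    c("q_room", "before", "q_before"), c("q_before", "the", "q_before_the"),
    c("q_before_the", "room", "q_room2"), c("q_room2", "with", "q_with"),
    c("q_with", "the", "q_with_the"),
    c("q_with_the", "red", "q_red"), c("q_with_the", "blue", "q_blue"),
    c("q_red", "pyramid", "A_before_red_pyramid"),
    c("q_red", "stalactite", "A_before_red_stalactite"),
    c("q_blue", "pyramid", "A_before_blue_pyramid"),
    c("q_blue", "stalactite", "A_before_blue_stalactite"))
  em <- do.call(rbind, edges)
  states <- unique(c("root", em[, 1], em[, 3], "REJECT"))
  # total transition table: reject sink everywhere a trie edge is absent
  transition <- expand.grid(state = states, symbol = lexicon,
                            stringsAsFactors = FALSE)
  transition$next_state <- "REJECT"
  key <- paste(transition$state, transition$symbol)
  transition$next_state[match(paste(em[, 1], em[, 2]), key)] <- em[, 3]
  accepts <- list(
    A_stop = list(goal = "stop"), A_explore = list(goal = "explore"),
    A_turn_left = list(goal = "turn_left"),
    A_turn_right = list(goal = "turn_right"),
    A_move_forward = list(goal = "move_forward"),
    A_move_backward = list(goal = "move_backward"),
    A_move_left = list(goal = "move_left"),
    A_move_right = list(goal = "move_right"),
    A_toward_pyramid = list(goal = "turn_toward", kind = "pyramid"),
    A_toward_stalactite = list(goal = "turn_toward", kind = "stalactite"),
    A_box = list(goal = "approach_box"),
    A_before_red_pyramid = list(goal = "move_before", color = "red",
                                kind = "pyramid"),
    A_before_red_stalactite = list(goal = "move_before", color = "red",
                                   kind = "stalactite"),
    A_before_blue_pyramid = list(goal = "move_before", color = "blue",
                                 kind = "pyramid"),
    A_before_blue_stalactite = list(goal = "move_before", color = "blue",
                                    kind = "stalactite"))
  # enumerate the sentence set by walking the trie
  sentences <- character(0)
  walk <- function(state, path) {
    if (state %in% names(accepts))
      sentences <<- c(sentences, paste(path, collapse = " "))
    hit <- em[, 1] == state
    for (i in which(hit)) walk(em[i, 3], c(path, em[i, 2]))
  }
  walk("root", character(0))
  structure(list(lexicon = lexicon, states = states, transition = transition,
                 start = "root", accepts = accepts,
                 sentences = unique(sentences)),
            class = "command_grammar")
}

tokenize_command <- function(text) {
  text <- tolower(trimws(text))
  text <- gsub("[[:punct:]]+$", "", text)
  if (!nzchar(text)) return(character(0))
  strsplit(text, "\\s+")[[1]]
}

parse_result <- function(goal = NULL, color = NULL, kind = NULL,
                         accepted = FALSE, reason = NULL) {
  structure(list(goal = goal, color = color, kind = kind,
                 accepted = accepted, reason = reason),
            class = "parse_result")
}

#' Symbolic parse oracle
#'
#' Runs the abstract grammar automaton over a command string, with no
#' neurons involved: the independent reference for [parse_command()].
#'
#' @param text a command string.
#' @param grammar a [command_grammar()].
#' @return a `parse_result` with fields `goal`, `color`, `kind`, `accepted`.
#' @export
parse_oracle <- function(text, grammar = command_grammar()) {
  toks <- tokenize_command(text)
  if (!length(toks)) return(parse_result(reason = "empty input"))
  if (!all(toks %in% grammar$lexicon))
    return(parse_result(reason = paste0("token outside lexicon: '",
                                        toks[!toks %in% grammar$lexicon][1], "'")))
  final <- fsa_oracle(grammar$transition, grammar$start, toks)
  acc <- grammar$accepts[[final]]
  if (is.null(acc)) return(parse_result(reason = "not a sentence"))
  parse_result(goal = acc$goal, color = acc$color, kind = acc$kind,
               accepted = TRUE)
}

#' Build the neural command parser
#'
#' Realizes the grammar automaton with one five-neuron cell assembly per
#' state (see [make_fsa()]); tokens are presented one settle window apart.
#'
#' @param net a [network()].
#' @param grammar a [command_grammar()].
#' @return a `cabot_fsa` with the grammar attached.
#' @export
build_parser <- function(net, grammar = command_grammar()) {
  fsa <- make_fsa(net, grammar$states, grammar$lexicon, grammar$transition,
                  grammar$start, id = "parser")
  fsa$grammar <- grammar
  fsa
}

#' Parse a command with the neural parser
#'
#' Lowercases and whitespace-tokenizes the input, resets the parser FSA to
#' its start state, presents the tokens one settle window apart, and reads
#' the accepting state.  Tokens outside the lexicon and empty input are
#' rejected without driving the network.
#'
#' @param text a command string.
#' @param parser a parser from [build_parser()].
#' @return a `parse_result`; when accepted, `goal` (and `color`/`kind` where
#'   applicable) identify the goal assembly to ignite.
#' @export
parse_command <- function(text, parser) {
  grammar <- parser$grammar
  toks <- tokenize_command(text)
  if (!length(toks)) return(parse_result(reason = "empty input"))
  if (!all(toks %in% grammar$lexicon))
    return(parse_result(reason = paste0("token outside lexicon: '",
                                        toks[!toks %in% grammar$lexicon][1], "'")))
  fsa_reset(parser)
  rec <- NULL
  for (a in toks) rec <- fsa_present(parser, a)
  final <- fsa_state(parser, rec)
  if (length(final) != 1) return(parse_result(reason = "no single final state"))
  acc <- grammar$accepts[[final]]
  if (is.null(acc)) return(parse_result(reason = "not a sentence"))
  parse_result(goal = acc$goal, color = acc$color, kind = acc$kind,
               accepted = TRUE)
}
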