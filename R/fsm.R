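#' The four mental commands
#'
#' Symbols of the controller alphabet: imagined left hand, right hand, both
#' hands, and rest. The cursor-task class names map onto them as RIGHT ->
#' right hand, LEFT -> left hand, UP/BOTH -> both hands, DOWN/REST -> rest.
#'
#' @return character vector of the four command symbols.
#' @export
bci_commands <- function() c("LEFT_HAND", "RIGHT_HAND", "BOTH_HANDS", "REST")

#' Map motor-imagery class labels to controller commands
#'
#' @param mi_class labels among `LEFT`, `RIGHT`, `BOTH`/`UP`, `REST`/`DOWN`.
#' @return commands from [bci_commands()].
#' @export
mi_class_to_command <- function(mi_class) {
  map <- c(LEFT = "LEFT_HAND", RIGHT = "RIGHT_HAND",
           BOTH = "BOTH_HANDS", UP = "BOTH_HANDS",
           REST = "REST", DOWN = "REST")
  out <- map[as.character(mi_class)]
  if (anyNA(out)) stop("unknown motor-imagery class: ",
                       mi_class[which(is.na(out))[1]])
  unname(out)
}

#' Build a command finite-state machine
#'
#' A deterministic FSM over the four mental commands. The transition table
#' must be total (every state x command pair defined) and the `MAIN` state
#' must be reachable from every state; both are validated at construction.
#' Actions are plain labels: the FSM performs no side effects, and states
#' flagged `text_entry` tell the caller to hand off to the P300 speller for
#' text input.
#'
#' @param transitions data.frame with columns `state`, `command`,
#'   `next_state`, `action`.
#' @param text_entry character vector of text-entry state names.
#' @param initial initial state (default `"MAIN"`).
#' @return object of class `command_fsm` with an empty trace.
#' @export
command_fsm <- function(transitions, text_entry = character(0),
                        initial = "MAIN") {
  req <- c("state", "command", "next_state", "action")
  stopifnot(all(req %in% names(transitions)))
  states <- sort(unique(c(transitions$state, transitions$next_state)))
  if (!"MAIN" %in% states) stop("FSM must contain a MAIN state")
  if (!initial %in% states) stop("initial state not in table: ", initial)
  bad_cmd <- setdiff(unique(transitions$command), bci_commands())
  if (length(bad_cmd) > 0) stop("unknown command(s): ",
                                paste(bad_cmd, collapse = ", "))
  # totality
  have <- paste(transitions$state, transitions$command)
  need <- as.vector(outer(states, bci_commands(), paste))
  gaps <- setdiff(need, have)
  if (length(gaps) > 0) {
    stop("transition table is not total; missing: ",
         paste(gaps, collapse = "; "))
  }
  if (anyDuplicated(have)) {
    stop("duplicate transition for: ", have[duplicated(have)][1])
  }
  # MAIN reachable from every state: BFS on reversed edges from MAIN
  reach <- "MAIN"
  repeat {
    more <- unique(transitions$state[transitions$next_state %in% reach])
    new <- setdiff(more, reach)
    if (length(new) == 0) break
    reach <- c(reach, new)
  }
  unreachable <- setdiff(states, reach)
  if (length(unreachable) > 0) {
    stop("MAIN is not reachable from: ", paste(unreachable, collapse = ", "))
  }
  structure(list(states = states,
                 transitions = transitions,
                 text_entry = intersect(text_entry, states),
                 current = initial,
                 trace = data.frame(from = character(0), command = character(0),
                                    to = character(0), action = character(0),
                                    stringsAsFactors = FALSE)),
            class = "command_fsm")
}

#' @export
print.command_fsm <- function(x, ...) {
  cat(sprintf("<command_fsm> %d states, current=%s, trace length %d\n",
              length(x$states), x$current, nrow(x$trace)))
  invisible(x)
}

#' Advance the FSM by one command
#'
#' Deterministic lookup in the transition table; the trace is extended with
#' the (from, command, to, action) record. No side effects beyond the
#' returned object.
#'
#' @param fsm a `command_fsm`.
#' @param command one of [bci_commands()].
#' @return list with the updated `fsm`, the new `state`, the emitted
#'   `action`, and `text_entry` (whether the new state requests speller
#'   handoff).
#' @export
fsm_step <- function(fsm, command) {
  stopifnot(inherits(fsm, "command_fsm"))
  if (!command %in% bci_commands()) stop("unknown command: ", command)
  row <- fsm$transitions[fsm$transitions$state == fsm$current &
                           fsm$transitions$command == command, ]
  rec <- data.frame(from = fsm$current, command = command,
                    to = row$next_state, action = row$action,
                    stringsAsFactors = FALSE)
  fsm$trace <- rbind(fsm$trace, rec)
  fsm$current <- row$next_state
  list(fsm = fsm, state = row$next_state, action = row$action,
       text_entry = row$next_state %in% fsm$text_entry)
}

#' Run a command sequence through the FSM
#'
#' Left-fold of [fsm_step()] over the sequence; the trace grows by one row
#' per command.
#'
#' @param fsm a `command_fsm`.
#' @param commands character vector of commands.
#' @return the updated `command_fsm`.
#' @export
fsm_run <- function(fsm, commands) {
  for (cmd in commands) fsm <- fsm_step(fsm, cmd)$fsm
  fsm
}

#' Write an FSM trace as TSV
#'
#' @param fsm a `command_fsm`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(fsm, path) {
  write.table(fsm$trace, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load an FSM from a YAML table
#'
#' Expected structure: `initial` (state name), `text_entry` (list of state
#' names), and `transitions`, a map state -> command -> `{to, action}`.
#' Totality and MAIN-reachability are validated at load and any gaps are
#' reported by name.
#'
#' @param path YAML file.
#' @return a [command_fsm()].
#' @export
load_fsm <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$transitions)) stop("FSM config lacks a 'transitions' map")
  rows <- list()
  for (st in names(cfg$transitions)) {
    for (cmd in names(cfg$transitions[[st]])) {
      tr <- cfg$transitions[[st]][[cmd]]
      rows[[length(rows) + 1]] <- data.frame(
        state = st, command = cmd,
        next_state = tr$to, action = tr$action %||% "noop",
        stringsAsFactors = FALSE)
    }
  }
  command_fsm(do.call(rbind, rows),
              text_entry = unlist(cfg$text_entry) %||% character(0),
              initial = cfg$initial %||% "MAIN")
}

#' The default controller table
#'
#' The shipped application FSM: from `MAIN`, imagining the right hand opens
#' the internet browser, the left hand opens the OS explorer, and both hands
#' open the email client whose inbox is then entered with both hands again.
#' REST consistently backs out toward `MAIN`. Compose/address states are
#' flagged for P300 text entry. Everything beyond the four documented
#' transitions is a configurable completion of the table (see the shipped
#' YAML for per-row provenance comments).
#'
#' @return a [command_fsm()].
#' @export
default_fsm <- function() {
  load_fsm(system.file("extdata", "fsm_default.yaml", package = "bcichain"))
}
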