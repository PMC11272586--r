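#' Effort level to force threshold mapping
#'
#' Integer effort levels 2--6 index the five force thresholds used in the
#' grip-force task, 30\% to 70\% of a subject's maximum voluntary contraction
#' (MVC) in 10\% steps.
#'
#' @param level integer vector of effort levels in 2..6.
#' @return numeric vector of required force thresholds, in percent of MVC.
#' @export
#' @examples
#' effort_pct_mvc(2:6)
effort_pct_mvc <- function(level) {
  if (!all(level %in% 2:6)) stop("effort levels must be integers in 2..6")
  10 * level + 10
}

REWARD_CREDITS <- seq(2L, 10L, by = 2L)
EFFORT_LEVELS <- 2:6
REST_CREDITS <- 1L
RECIPIENTS <- c("self", "other")

#' Build a balanced factorial trial schedule
#'
#' Constructs the work-vs-rest decision schedule: a full crossing of
#' recipient (self, other), five effort levels (30--70\% MVC) and five reward
#' magnitudes (2--10 credits, rest fixed at 1 credit), each cell repeated
#' `n_reps` times.  With the default three repetitions this gives 75 trials
#' per recipient (150 in total), split into three blocks.  Recipients are
#' interleaved by shuffling trials uniformly within each block while keeping
#' per-block recipient counts as equal as possible.
#'
#' @param n_reps repetitions of each (recipient, effort, reward) cell;
#'   default 3.
#' @param seed integer seed controlling the shuffle; the schedule is a pure
#'   function of `(n_reps, seed)`.
#' @param n_blocks number of blocks; default 3.
#' @return a `data.frame` of class `trial_schedule` with columns
#'   `trial_index`, `block`, `recipient`, `effort_level`, `effort_pct_mvc`,
#'   `reward_credits`, `rest_credits`, and attributes `seed`, `n_reps`.
#' @export
#' @examples
#' sched <- build_schedule(n_reps = 3, seed = 7)
#' table(sched$recipient)
build_schedule <- function(n_reps = 3, seed = 1, n_blocks = 3) {
  if (length(n_reps) != 1 || is.na(n_reps) || n_reps < 1 || n_reps != round(n_reps))
    stop("n_reps must be a positive integer")
  cells <- expand.grid(
    recipient = RECIPIENTS, effort_level = EFFORT_LEVELS,
    reward_credits = REWARD_CREDITS,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  trials <- cells[rep(seq_len(nrow(cells)), times = n_reps), ]
  with_local_seed(seed, function() {
    per_rec <- split(trials, trials$recipient)
    # equalized block assignment per recipient, then shuffle within block
    out <- lapply(per_rec, function(tr) {
      n <- nrow(tr)
      blocks <- rep(seq_len(n_blocks), length.out = n)[order(runif(n))]
      tr$block <- sort(blocks)
      tr[sample.int(n), ]
    })
    all <- do.call(rbind, out)
    all <- all[order(all$block, runif(nrow(all))), ]
    all$trial_index <- seq_len(nrow(all))
    all$effort_pct_mvc <- effort_pct_mvc(all$effort_level)
    all$rest_credits <- REST_CREDITS
    rownames(all) <- NULL
    all <- all[, c("trial_index", "block", "recipient", "effort_level",
                   "effort_pct_mvc", "reward_credits", "rest_credits")]
    attr(all, "seed") <- seed
    attr(all, "n_reps") <- n_reps
    class(all) <- c("trial_schedule", "data.frame")
    all
  })
}

#' Validate a trial schedule
#'
#' Checks the structural invariants of a schedule: per-cell balance, valid
#' effort/reward codes and the bijective effort-to-force mapping.
#'
#' @param schedule a data frame as returned by [build_schedule()].
#' @return invisibly `TRUE`; signals an error describing the first violated
#'   invariant otherwise.
#' @export
validate_schedule <- function(schedule) {
  stopifnot(is.data.frame(schedule))
  need <- c("recipient", "effort_level", "reward_credits")
  if (!all(need %in% names(schedule)))
    stop("schedule must have columns: ", paste(need, collapse = ", "))
  if (!all(schedule$recipient %in% RECIPIENTS)) stop("unknown recipient label")
  if (!all(schedule$effort_level %in% EFFORT_LEVELS)) stop("effort_level out of range")
  if (!all(schedule$reward_credits %in% REWARD_CREDITS)) stop("reward_credits out of range")
  counts <- table(schedule$recipient, schedule$effort_level, schedule$reward_credits)
  if (length(unique(as.vector(counts))) != 1)
    stop("schedule cells are not balanced")
  invisible(TRUE)
}

#' Write / read a schedule as delimited text
#'
#' @param schedule a trial schedule.
#' @param path file path for the CSV.
#' @export
write_schedule <- function(schedule, path) {
  write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("trial_schedule", "data.frame")
  out
}
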