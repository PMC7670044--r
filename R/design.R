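#' Design parameters for a recognition-memory experiment
#'
#' Bundles the structural and timing parameters of the study/test design:
#' a pool of words split into equal lists, a study phase in which half the
#' studied words are presented once (1x) and half three times (3x), and a
#' scanned test phase of \code{n_runs} runs. Each test run presents
#' \code{n_1x} once-studied, \code{n_3x} thrice-studied and \code{n_new}
#' unstudied words plus \code{n_null} null events, with jittered
#' inter-trial intervals. Half the runs reward "old" responses more
#' (incentivize-old) and half reward "new" responses more (incentivize-new).
#'
#' @param n_subjects number of subjects in a simulated cohort.
#' @param pool_size total number of words in the pool.
#' @param n_lists number of equal-sized word lists (half concrete, half
#'   abstract); must divide \code{pool_size}.
#' @param n_runs number of test runs; must be even so that run types can be
#'   balanced.
#' @param n_1x,n_3x,n_new per-run counts of once-studied, thrice-studied and
#'   new words.
#' @param n_null per-run count of null (fixation-string) events.
#' @param study_word_ms,study_fix_ms study-phase word and fixation durations.
#' @param test_fix_ms,test_word_ms test-phase fixation and word durations.
#' @param iti_range_ms length-2 numeric, uniform jitter range for the
#'   inter-trial interval in ms.
#' @param payoff_high,payoff_low points awarded for the incentivized and
#'   non-incentivized correct response.
#'
#' @return An object of class \code{design_params} (a list).
#' @export
design_params <- function(n_subjects = 14L,
                          pool_size = 512L,
                          n_lists = 8L,
                          n_runs = 8L,
                          n_1x = 16L, n_3x = 16L, n_new = 32L,
                          n_null = 4L,
                          study_word_ms = 2800, study_fix_ms = 200,
                          test_fix_ms = 500, test_word_ms = 3000,
                          iti_range_ms = c(2000, 6000),
                          payoff_high = 5, payoff_low = 1) {
  if (pool_size %% n_lists != 0L)
    stop("pool_size must be divisible by n_lists", call. = FALSE)
  if (n_lists %% 2L != 0L)
    stop("n_lists must be even (half concrete, half abstract)", call. = FALSE)
  if (n_runs %% 2L != 0L)
    stop("n_runs must be even (half incentivize-old, half incentivize-new)",
         call. = FALSE)
  if (length(iti_range_ms) != 2L || iti_range_ms[1] >= iti_range_ms[2])
    stop("iti_range_ms must be an increasing length-2 range", call. = FALSE)
  words_per_run <- n_1x + n_3x + n_new
  n_studied <- (n_1x + n_3x) * n_runs
  n_unstudied <- n_new * n_runs
  if (n_studied + n_unstudied != pool_size)
    stop("per-run counts times n_runs must exhaust the pool: ",
         n_studied + n_unstudied, " != ", pool_size, call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects), pool_size = as.integer(pool_size),
    n_lists = as.integer(n_lists), n_runs = as.integer(n_runs),
    n_1x = as.integer(n_1x), n_3x = as.integer(n_3x),
    n_new = as.integer(n_new), n_null = as.integer(n_null),
    words_per_run = as.integer(words_per_run),
    study_word_ms = study_word_ms, study_fix_ms = study_fix_ms,
    test_fix_ms = test_fix_ms, test_word_ms = test_word_ms,
    iti_range_ms = as.numeric(iti_range_ms),
    payoff_high = payoff_high, payoff_low = payoff_low),
    class = "design_params")
}

#' Generate a synthetic word pool
#'
#' Creates \code{pool_size} synthetic word tokens (\code{w0001}, ...) split
#' into \code{n_lists} disjoint equal lists. The first half of the lists is
#' labelled concrete and the second half abstract; list membership is a
#' random partition of the pool so that repeated calls with different seeds
#' give different assignments.
#'
#' @param params a \code{\link{design_params}} object.
#' @param seed optional integer seed for reproducibility.
#' @return A data frame with columns \code{word}, \code{list_id},
#'   \code{category}.
#' @export
generate_word_pool <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- params$pool_size
  list_size <- n %/% params$n_lists
  words <- sprintf("w%04d", seq_len(n))
  # random partition into lists; category is tied to the list
  order <- sample.int(n)
  list_id <- integer(n)
  list_id[order] <- rep(seq_len(params$n_lists), each = list_size)
  category <- ifelse(list_id <= params$n_lists %/% 2L, "concrete", "abstract")
  data.frame(word = words, list_id = list_id, category = category,
             stringsAsFactors = FALSE)
}

studied_lists <- function(params, counterbalance_id) {
  # counterbalance over two designs: odd ids study the first half of the
  # concrete lists plus the first half of the abstract lists, even ids the
  # complement, so each list is studied in exactly one of the two designs
  half <- params$n_lists %/% 2L
  quarter <- half %/% 2L
  first <- c(seq_len(quarter), half + seq_len(quarter))
  if (counterbalance_id %% 2L == 1L) first else setdiff(seq_len(params$n_lists), first)
}

# split x randomly into n_groups equal chunks; returns list of vectors
split_random <- function(x, n_groups) {
  stopifnot(length(x) %% n_groups == 0L)
  x <- sample(x)
  split(x, rep(seq_len(n_groups), each = length(x) %/% n_groups))
}

#' Generate a counterbalanced study/test design
#'
#' Assigns half the word lists (balanced over categories) to studied status
#' according to \code{counterbalance_id}, splits the studied words into 1x
#' and 3x items, and allocates words to test runs so that every run contains
#' exactly the per-run counts of 1x, 3x and new items, balanced over
#' concrete/abstract categories. Null events are interleaved at random
#' positions and inter-trial intervals are drawn uniformly from the
#' configured jitter range.
#'
#' @param pool a word pool from \code{\link{generate_word_pool}}.
#' @param params a \code{\link{design_params}} object.
#' @param counterbalance_id integer; designs with ids of opposite parity
#'   swap studied and unstudied lists.
#' @param seed optional integer seed.
#' @return An object of class \code{experiment_design}: a list with
#'   \code{study_list} (data frame \code{word}, \code{repetitions}),
#'   \code{runs} (list of per-run trial data frames with \code{trial},
#'   \code{onset_ms}, \code{duration_ms}, \code{item_type}, \code{word}),
#'   \code{run_type} (character vector per run) and
#'   \code{counterbalance_id}.
#' @export
generate_design <- function(pool, params, counterbalance_id = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  studied <- studied_lists(params, counterbalance_id)
  if (params$n_1x %% 2L || params$n_3x %% 2L || params$n_new %% 2L)
    stop("per-run counts must be even to balance concrete/abstract",
         call. = FALSE)

  stud_words <- pool[pool$list_id %in% studied, ]
  new_words <- pool[!pool$list_id %in% studied, ]
  if (nrow(stud_words) != (params$n_1x + params$n_3x) * params$n_runs)
    stop("pool too small for the requested runs", call. = FALSE)

  # within each category, split studied words evenly into 1x and 3x
  assign_reps <- function(w) {
    k <- length(w) %/% 2L
    w1 <- sample(w, k)
    data.frame(word = w, repetitions = ifelse(w %in% w1, 1L, 3L),
               stringsAsFactors = FALSE)
  }
  reps <- do.call(rbind, lapply(split(stud_words$word, stud_words$category),
                                assign_reps))
  rownames(reps) <- NULL
  study_list <- reps[sample.int(nrow(reps)), ]
  rownames(study_list) <- NULL

  # allocate words to runs, balancing category within each item type
  alloc <- list()
  for (cat in c("concrete", "abstract")) {
    w1 <- study_list$word[study_list$repetitions == 1L &
                            study_list$word %in% stud_words$word[stud_words$category == cat]]
    w3 <- study_list$word[study_list$repetitions == 3L &
                            study_list$word %in% stud_words$word[stud_words$category == cat]]
    wn <- new_words$word[new_words$category == cat]
    alloc[[paste0("1x_", cat)]] <- split_random(w1, params$n_runs)
    alloc[[paste0("3x_", cat)]] <- split_random(w3, params$n_runs)
    alloc[[paste0("new_", cat)]] <- split_random(wn, params$n_runs)
  }

  run_type <- sample(rep(c("incentivize-old", "incentivize-new"),
                         each = params$n_runs %/% 2L))

  runs <- vector("list", params$n_runs)
  for (r in seq_len(params$n_runs)) {
    words <- c(alloc[["1x_concrete"]][[r]], alloc[["1x_abstract"]][[r]],
               alloc[["3x_concrete"]][[r]], alloc[["3x_abstract"]][[r]],
               alloc[["new_concrete"]][[r]], alloc[["new_abstract"]][[r]])
    types <- rep(c("1x", "3x", "new"),
                 times = c(params$n_1x, params$n_3x, params$n_new))
    ord <- sample.int(length(words))
    words <- words[ord]; types <- types[ord]
    # interleave null events at random positions
    n_tot <- length(words) + params$n_null
    null_pos <- sort(sample.int(n_tot, params$n_null))
    item_type <- character(n_tot); word <- character(n_tot)
    item_type[null_pos] <- "null"; word[null_pos] <- NA_character_
    item_type[item_type == ""] <- types
    word[!seq_len(n_tot) %in% null_pos] <- words

    iti <- stats::runif(n_tot, params$iti_range_ms[1], params$iti_range_ms[2])
    onset <- numeric(n_tot)
    t_cursor <- 0
    for (i in seq_len(n_tot)) {
      t_cursor <- t_cursor + params$test_fix_ms
      onset[i] <- t_cursor
      t_cursor <- t_cursor + params$test_word_ms + iti[i]
    }
    runs[[r]] <- data.frame(trial = seq_len(n_tot), onset_ms = onset,
                            duration_ms = params$test_word_ms,
                            item_type = item_type, word = word,
                            stringsAsFactors = FALSE)
  }

  structure(list(study_list = study_list, runs = runs, run_type = run_type,
                 counterbalance_id = as.integer(counterbalance_id),
                 params = params),
            class = "experiment_design")
}

#' Write per-run event tables
#'
#' Writes one tab-separated events file per run with columns
#' \code{onset_ms}, \code{duration_ms}, \code{trial_type}, \code{word},
#' \code{run_type}.
#'
#' @param design an \code{experiment_design}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_events_tsv <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(design$runs))
  for (r in seq_along(design$runs)) {
    ev <- design$runs[[r]]
    out <- data.frame(onset_ms = ev$onset_ms, duration_ms = ev$duration_ms,
                      trial_type = ev$item_type, word = ev$word,
                      run_type = design$run_type[r])
    paths[r] <- file.path(dir, sprintf("run-%02d_events.tsv", r))
    utils::write.table(out, paths[r], sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(paths)
}
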