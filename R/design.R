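#' Factor levels used throughout the package
#'
#' Plausibility, congruency, order and counterbalance are two-level factors.
#' The level order here fixes the contrast coding used by [code_contrasts()]:
#' the first level of each pair codes +0.5.
#'
#' @keywords internal
#' @name factor-levels
PLAUSIBILITY_LEVELS <- c("plausible", "implausible")
CONGRUENCY_LEVELS <- c("congruent", "incongruent")
ORDER_LEVELS <- c("scene_first", "sentence_first")
COUNTERBALANCE_LEVELS <- c("yes_left", "yes_right")

condition_cells <- function() {
  # fixed order of the four plausibility x congruency cells
  expand.grid(
    plausibility = PLAUSIBILITY_LEVELS,
    congruency = CONGRUENCY_LEVELS,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Build the full item bank of a plausibility-by-congruency design
#'
#' Every base scene is crossed with the two levels of plausibility and the
#' two levels of congruency, yielding four items per scene (e.g. 225 scenes
#' give 900 items).
#'
#' @param n_scenes number of base scenes (positive integer).
#' @return a data.frame of class `item_bank` with columns `scene_id`,
#'   `plausibility`, `congruency`; one row per item, `4 * n_scenes` rows.
#' @examples
#' bank <- build_item_bank(225)
#' nrow(bank) # 900
#' @export
build_item_bank <- function(n_scenes) {
  if (length(n_scenes) != 1 || is.na(n_scenes) || n_scenes < 1 ||
      n_scenes != as.integer(n_scenes)) {
    stop("`n_scenes` must be a single positive integer", call. = FALSE)
  }
  n_scenes <- as.integer(n_scenes)
  cells <- condition_cells()
  bank <- data.frame(
    scene_id = rep(seq_len(n_scenes), each = nrow(cells)),
    plausibility = rep(cells$plausibility, times = n_scenes),
    congruency = rep(cells$congruency, times = n_scenes),
    stringsAsFactors = FALSE
  )
  bank$cell <- paste(bank$plausibility, bank$congruency, sep = "/")
  class(bank) <- c("item_bank", "data.frame")
  bank
}

#' Partition an item bank into Latin-square lists
#'
#' Items are assigned to lists by a Latin rotation over the four condition
#' cells, so that (i) the lists partition the bank, (ii) no scene occurs
#' twice within a list, and (iii) across the lists every scene contributes
#' each condition cell exactly once. A seed applies an extra random cyclic
#' offset per scene; the default (`seed = NULL`) uses the deterministic
#' rotation by scene index.
#'
#' @param bank an [build_item_bank()] result.
#' @param n_lists number of lists; must equal the number of condition cells
#'   (4) and divide the bank size.
#' @param seed optional integer seed for the per-scene rotation offsets.
#' @return list of data.frames (one per list), class `latin_lists`.
#' @export
build_latin_lists <- function(bank, n_lists = 4L, seed = NULL) {
  stopifnot(inherits(bank, "data.frame"))
  n_cells <- nrow(condition_cells())
  if (n_lists != n_cells) {
    stop("`n_lists` must equal the number of condition cells (", n_cells, ")",
         call. = FALSE)
  }
  if (nrow(bank) %% n_lists != 0) {
    stop("bank size (", nrow(bank), ") is not divisible by `n_lists`",
         call. = FALSE)
  }
  scenes <- sort(unique(bank$scene_id))
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    offsets <- sample.int(n_lists, length(scenes), replace = TRUE) - 1L
  } else {
    offsets <- seq_along(scenes) %% n_lists
  }
  names(offsets) <- as.character(scenes)
  cells <- condition_cells()
  cell_key <- paste(cells$plausibility, cells$congruency, sep = "/")
  cell_index <- match(paste(bank$plausibility, bank$congruency, sep = "/"),
                      cell_key) - 1L
  list_id <- ((offsets[as.character(bank$scene_id)] + cell_index) %% n_lists) + 1L
  out <- lapply(seq_len(n_lists), function(l) {
    li <- bank[list_id == l, , drop = FALSE]
    rownames(li) <- NULL
    attr(li, "list_id") <- l
    li
  })
  class(out) <- c("latin_lists", "list")
  out
}

#' Build balanced participant schedules
#'
#' Assigns each participant to one Latin list, an order-of-presentation
#' level and a yes-button side (both split as evenly as possible across
#' participants and crossed with list assignment), then samples
#' `per_participant` items from the assigned list with condition cells
#' balanced (`per_participant / 4` per cell when divisible). Within each
#' list the per-cell item queues are consumed cyclically across
#' participants, so across all schedules every bank item is used an equal
#' number of times up to remainder. Trial order is randomized per
#' participant.
#'
#' @param lists a [build_latin_lists()] result.
#' @param n_participants number of participants.
#' @param per_participant trials per participant; must not exceed the list
#'   size.
#' @param seed integer seed for item sampling and trial-order shuffling.
#' @return list of schedules (class `schedules`); each schedule is a list
#'   with `participant_id`, `list_id`, `order`, `counterbalance` and a
#'   `trials` data.frame.
#' @export
build_schedules <- function(lists, n_participants, per_participant, seed = 1L) {
  stopifnot(inherits(lists, "latin_lists"), n_participants >= 1,
            per_participant >= 1)
  n_lists <- length(lists)
  list_size <- nrow(lists[[1]])
  if (per_participant > list_size) {
    stop("`per_participant` (", per_participant,
         ") exceeds the list size (", list_size, ")", call. = FALSE)
  }
  set.seed(substream_seed(seed, "design"))
  cells <- condition_cells()
  cell_key <- paste(cells$plausibility, cells$congruency, sep = "/")
  # per list: shuffled item queue per condition cell, consumed cyclically
  queues <- lapply(lists, function(li) {
    lapply(cell_key, function(k) {
      idx <- which(paste(li$plausibility, li$congruency, sep = "/") == k)
      idx[sample.int(length(idx))]
    })
  })
  cursors <- lapply(queues, function(q) rep(0L, length(q)))

  base_n <- per_participant %/% 4L
  extra <- per_participant %% 4L

  schedules <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    i <- p - 1L
    l <- (i %% n_lists) + 1L
    order_lv <- ORDER_LEVELS[((i %/% n_lists) %% 2L) + 1L]
    cb_lv <- COUNTERBALANCE_LEVELS[((i %/% (n_lists * 2L)) %% 2L) + 1L]
    need <- rep(base_n, 4L)
    if (extra > 0) {
      # rotate which cells take the remainder so cells stay balanced overall
      bump <- ((i + seq_len(extra) - 1L) %% 4L) + 1L
      need[bump] <- need[bump] + 1L
    }
    rows <- integer(0)
    for (k in seq_len(4L)) {
      if (need[k] == 0L) next
      q <- queues[[l]][[k]]
      if (need[k] > length(q)) {
        stop("cell '", cell_key[k], "' in list ", l, " has only ", length(q),
             " items; cannot supply ", need[k], " per participant",
             call. = FALSE)
      }
      pos <- ((cursors[[l]][k] + seq_len(need[k]) - 1L) %% length(q)) + 1L
      cursors[[l]][k] <- (cursors[[l]][k] + need[k]) %% length(q)
      rows <- c(rows, q[pos])
    }
    trials <- lists[[l]][rows[sample.int(length(rows))],
                         c("scene_id", "plausibility", "congruency")]
    rownames(trials) <- NULL
    class(trials) <- "data.frame"
    schedules[[p]] <- list(
      participant_id = p,
      list_id = l,
      order = order_lv,
      counterbalance = cb_lv,
      trials = trials
    )
  }
  class(schedules) <- c("schedules", "list")
  schedules
}

#' @export
print.schedules <- function(x, ...) {
  cat(length(x), "participant schedules;",
      sum(vapply(x, function(s) nrow(s$trials), 1L)), "scheduled trials\n")
  invisible(x)
}

#' @export
print.item_bank <- function(x, ...) {
  cat("item bank:", length(unique(x$scene_id)), "scenes x 4 cells =",
      nrow(x), "items\n")
  invisible(x)
}
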