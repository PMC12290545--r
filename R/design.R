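#' Specify the structure of a timeline memory experiment
#'
#' A design specification captures the structural constants of a
#' boundary-segmented encoding session: how many items are presented, how
#' long each color context is, which within-context positions are probed in
#' the timeline task, how many sessions (one per stimulation condition) each
#' participant completes, and how large the image pool is.
#'
#' Defaults reproduce the canonical design: 72 items per session segmented
#' into 9 color contexts of 8 items, with the 1st (boundary), 3rd, 5th, and
#' 7th item of every context probed, three stimulation conditions (sham,
#' slow-theta 3 Hz, fast-theta 8 Hz), a 371-image pool, and 24 participants
#' (a multiple of the 3! = 6 condition orderings needed for counterbalancing).
#'
#' @param n_items_per_session Items presented per encoding session; must be a
#'   positive multiple of `context_length`.
#' @param context_length Items per color context (one context = one event).
#' @param tested_within_positions Within-context positions probed in the
#'   timeline task; subset of `1:context_length`.
#' @param n_sessions Encoding sessions per participant (one per condition).
#' @param image_pool_size Size of the image pool items are drawn from.
#' @param n_participants Number of participants; must be a multiple of
#'   `factorial(length(conditions))` so condition orders counterbalance.
#' @param conditions Ordered character vector of condition labels.
#'
#' @return A `design_spec` object (a validated list).
#' @export
#' @examples
#' spec <- design_spec()
#' spec$n_contexts
design_spec <- function(n_items_per_session = 72,
                        context_length = 8,
                        tested_within_positions = c(1L, 3L, 5L, 7L),
                        n_sessions = 3,
                        image_pool_size = 371,
                        n_participants = 24,
                        conditions = c("sham", "slow_3hz", "fast_8hz")) {
  n_items_per_session <- assert_count(n_items_per_session, "n_items_per_session")
  context_length <- assert_count(context_length, "context_length")
  n_sessions <- assert_count(n_sessions, "n_sessions")
  image_pool_size <- assert_count(image_pool_size, "image_pool_size")
  n_participants <- assert_count(n_participants, "n_participants")
  if (n_items_per_session %% context_length != 0L) {
    abort(sprintf(
      "`n_items_per_session` (%d) must be a multiple of `context_length` (%d).",
      n_items_per_session, context_length))
  }
  tested_within_positions <- sort(unique(as.integer(tested_within_positions)))
  if (any(tested_within_positions < 1L) ||
      any(tested_within_positions > context_length)) {
    abort(sprintf(
      "`tested_within_positions` must lie in 1..%d (context length).",
      context_length))
  }
  conditions <- as.character(conditions)
  if (anyDuplicated(conditions) || length(conditions) < 1L) {
    abort("`conditions` must be distinct labels.")
  }
  if (length(conditions) != n_sessions) {
    abort("`n_sessions` must equal the number of conditions (one session each).")
  }
  n_orders <- factorial(length(conditions))
  if (n_participants %% n_orders != 0L) {
    abort(sprintf(
      "`n_participants` (%d) must be a multiple of the %d condition orderings (remainder %d).",
      n_participants, n_orders, n_participants %% n_orders))
  }
  structure(
    list(
      n_items_per_session = n_items_per_session,
      context_length = context_length,
      n_contexts = n_items_per_session %/% context_length,
      tested_within_positions = tested_within_positions,
      n_sessions = n_sessions,
      image_pool_size = image_pool_size,
      n_participants = n_participants,
      conditions = conditions
    ),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec>\n")
  cat(sprintf("  %d items/session in %d contexts of %d; probes at within positions {%s}\n",
              x$n_items_per_session, x$n_contexts, x$context_length,
              paste(x$tested_within_positions, collapse = ",")))
  cat(sprintf("  %d participants x %d sessions; conditions: %s; image pool %d\n",
              x$n_participants, x$n_sessions,
              paste(x$conditions, collapse = ", "), x$image_pool_size))
  invisible(x)
}

#' Built-in frame-color palette
#'
#' A fixed palette of maximally spaced RGB triples used for context frame
#' colors: the full 3x3x3 grid over channel values \{0, 128, 255\}, giving 27
#' distinct colors. Designs never need more than `n_contexts` colors per
#' session, and any user palette of distinct hex strings can be substituted.
#'
#' @param n Number of colors to return (at most 27 from the built-in grid).
#' @return Character vector of hex color strings.
#' @export
#' @examples
#' frame_palette(9)
frame_palette <- function(n = 27) {
  n <- assert_count(n, "n")
  grid <- expand.grid(r = c(0, 128, 255), g = c(0, 128, 255), b = c(0, 128, 255))
  pal <- grDevices::rgb(grid$r, grid$g, grid$b, maxColorValue = 255)
  if (n > length(pal)) {
    abort(sprintf("Built-in palette has %d colors; %d requested.", length(pal), n))
  }
  pal[seq_len(n)]
}

all_permutations <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

subject_ids <- function(n) sprintf("S%02d", seq_len(n))

#' Counterbalance condition orders across participants
#'
#' Assigns each participant one ordering of the stimulation conditions such
#' that all `k!` orderings are used equally often, with the assignment order
#' shuffled reproducibly by `seed`.
#'
#' @param n_participants Number of participants; must be divisible by `k!`.
#' @param conditions Character vector of condition labels.
#' @param seed Integer seed for the shuffle (or `NULL`).
#'
#' @return A tibble with one row per participant: `subject_id`, `order_id`
#'   (1..k!), `order` (conditions joined by `">"`), and `conditions`
#'   (list-column of character vectors, session order).
#' @export
#' @examples
#' counterbalance_orders(6, c("sham", "slow_3hz", "fast_8hz"), seed = 1)
counterbalance_orders <- function(n_participants,
                                  conditions = c("sham", "slow_3hz", "fast_8hz"),
                                  seed = NULL) {
  n_participants <- assert_count(n_participants, "n_participants")
  conditions <- as.character(conditions)
  perms <- all_permutations(conditions)
  k <- length(perms)
  if (n_participants %% k != 0L) {
    abort(sprintf(
      "`n_participants` (%d) is not divisible by %d condition orderings (remainder %d).",
      n_participants, k, n_participants %% k))
  }
  maybe_set_seed(seed)
  order_ids <- sample(rep(seq_len(k), each = n_participants %/% k))
  tibble(
    subject_id = subject_ids(n_participants),
    order_id = order_ids,
    order = vapply(perms[order_ids], paste, character(1), collapse = ">"),
    conditions = perms[order_ids]
  )
}

#' Generate encoding-trial designs for a full cohort
#'
#' Builds the complete encoding design for every participant: for each of the
#' counterbalanced sessions, items are laid out in serial positions
#' 1..`n_items_per_session`, segmented into color contexts of
#' `context_length` items. Frame colors are drawn without replacement within
#' a session; images are drawn without replacement from the pool across a
#' participant's sessions, so no image repeats for a participant.
#'
#' @param spec A [design_spec()].
#' @param seed Integer seed; the same seed reproduces the design exactly.
#' @param palette Vector of hex colors to draw context frames from; must have
#'   at least `n_contexts` entries. Defaults to [frame_palette()].
#'
#' @return A tibble of encoding trials: `subject_id`, `condition`,
#'   `session_order`, `serial_position`, `context_index`,
#'   `within_context_position`, `is_boundary`, `image_id`, `frame_color_hex`.
#' @export
#' @examples
#' design <- generate_design(design_spec(n_participants = 6), seed = 1)
#' dplyr::count(design, subject_id, session_order)
generate_design <- function(spec = design_spec(), seed = NULL,
                            palette = frame_palette()) {
  stopifnot(inherits(spec, "design_spec"))
  needed <- spec$n_sessions * spec$n_items_per_session
  if (spec$image_pool_size < needed) {
    abort(sprintf(
      "Image pool too small: %d images required (%d sessions x %d items) but only %d available.",
      needed, spec$n_sessions, spec$n_items_per_session, spec$image_pool_size))
  }
  if (length(palette) < spec$n_contexts) {
    abort(sprintf("Palette has %d colors; %d contexts require at least as many.",
                  length(palette), spec$n_contexts))
  }
  seeds <- derive_seeds(seed, 2L)
  orders <- counterbalance_orders(spec$n_participants, spec$conditions,
                                  seed = seeds[[1]])
  pool <- sprintf("img%04d", seq_len(spec$image_pool_size))

  maybe_set_seed(seeds[[2]])
  serial <- seq_len(spec$n_items_per_session)
  context <- (serial - 1L) %/% spec$context_length + 1L
  within <- (serial - 1L) %% spec$context_length + 1L

  per_subject <- lapply(seq_len(spec$n_participants), function(i) {
    imgs <- sample(pool, needed)
    sessions <- lapply(seq_len(spec$n_sessions), function(s) {
      cols <- sample(palette, spec$n_contexts)
      tibble(
        subject_id = orders$subject_id[i],
        condition = orders$conditions[[i]][s],
        session_order = s,
        serial_position = serial,
        context_index = context,
        within_context_position = within,
        is_boundary = within == 1L,
        image_id = imgs[(s - 1L) * spec$n_items_per_session + serial],
        frame_color_hex = cols[context]
      )
    })
    bind_rows(sessions)
  })
  bind_rows(per_subject)
}

#' Select timeline probe items for one encoding session
#'
#' Picks the items at the tested within-context positions of every context in
#' a single session and returns them in a randomized probe order.
#'
#' @param design Encoding trials of one subject-session (a tibble with
#'   `serial_position`, `context_index`, `within_context_position`).
#' @param spec The [design_spec()] the session was generated under.
#' @param seed Integer seed for the probe-order shuffle.
#'
#' @return A tibble with `probe_order`, `actual_position` (the probed serial
#'   position), `context_index`, `within_context_position`, `is_boundary`.
#' @export
select_test_items <- function(design, spec = design_spec(), seed = NULL) {
  assert_columns(design, c("serial_position", "context_index",
                           "within_context_position"), "`design`")
  if (any(spec$tested_within_positions > spec$context_length)) {
    abort("Tested within-context positions exceed the context length.")
  }
  probes <- design |>
    filter(.data$within_context_position %in% spec$tested_within_positions) |>
    transmute(
      actual_position = .data$serial_position,
      context_index = .data$context_index,
      within_context_position = .data$within_context_position,
      is_boundary = .data$within_context_position == 1L
    )
  maybe_set_seed(seed)
  probes <- probes[sample.int(nrow(probes)), , drop = FALSE]
  probes |>
    mutate(probe_order = row_number(), .before = 1) |>
    as_tibble()
}

#' Stimulation-protocol arithmetic
#'
#' Validates and completes the arithmetic of a sinusoidal stimulation
#' protocol: the total cycle count implied by frequency and duration, and the
#' ramp duration in seconds implied by a ramp length expressed in cycles.
#'
#' @param frequency Stimulation frequency in Hz (> 0).
#' @param duration Stimulation duration in minutes (> 0).
#' @param ramp_cycles Ramp-up/-down length in cycles (default 60).
#'
#' @return A one-row tibble: `frequency_hz`, `duration_min`, `n_cycles`
#'   (`round(duration * 60 * frequency)`), `ramp_cycles`, `ramp_seconds`
#'   (`ramp_cycles / frequency`).
#' @export
#' @examples
#' stim_protocol(3, 5.5)    # 990 cycles, 20 s ramp
#' stim_protocol(8, 5.5)    # 2640 cycles, 7.5 s ramp
#' stim_protocol(5.5, 0.5)  # 165 cycles (brief sham burst)
stim_protocol <- function(frequency, duration, ramp_cycles = 60) {
  if (!is.numeric(frequency) || length(frequency) != 1L || frequency <= 0) {
    abort("`frequency` must be a single positive number (Hz).")
  }
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    abort("`duration` must be a single positive number (minutes).")
  }
  ramp_cycles <- assert_count(ramp_cycles, "ramp_cycles", min = 0L)
  tibble(
    frequency_hz = frequency,
    duration_min = duration,
    n_cycles = round(duration * 60 * frequency),
    ramp_cycles = as.integer(ramp_cycles),
    ramp_seconds = ramp_cycles / frequency
  )
}
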