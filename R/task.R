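## Screen geometry (pixels). The screen is a 16-row x 32-column intensity
## grid. The two brightness squares are 4x4 blocks centered vertically, one
## in each half of the screen; the cue bar sits at the screen center, outside
## both square windows, so the subcortical receptive fields never see it.
.screen_rows <- 16L
.screen_cols <- 32L
.left_rows <- 7:10
.left_cols <- 7:10
.right_rows <- 7:10
.right_cols <- 23:26
## The two cue bars sit on the vertical midline at distinct, fixed
## positions (horizontal bar above center, vertical bar below), both well
## outside the two square windows. Distinct positions keep the rule cues
## linearly discriminable under heavy pixel noise.
.cue_pro <- cbind(row = c(4L, 4L), col = c(16L, 17L))   # horizontal 2x1 bar
.cue_anti <- cbind(row = c(11L, 12L), col = c(16L, 16L)) # vertical 1x2 bar

.blank_frame <- function(phase) {
  structure(matrix(0, .screen_rows, .screen_cols),
            phase = phase, class = c("saccadia_frame", "matrix", "array"))
}

#' Render a cue screen
#'
#' Draws the task-rule cue on an otherwise dark 16x32 screen: a horizontal
#' 2x1 bar of unit intensity for a prosaccade ("pro") trial, a vertical 1x2
#' bar for an antisaccade ("anti") trial. The bar is placed at the screen
#' center, outside both brightness-square windows.
#'
#' @param cue `"pro"` or `"anti"`.
#' @return A 16x32 numeric matrix of class `saccadia_frame` with
#'   `attr(, "phase") == "cue"`.
#' @examples
#' sum(render_cue("pro"))  # two unit-intensity pixels
#' @export
render_cue <- function(cue = c("pro", "anti")) {
  cue <- match.arg(cue)
  f <- .blank_frame("cue")
  px <- if (cue == "pro") .cue_pro else .cue_anti
  f[px] <- 1
  f
}

#' Render a brightness-comparison screen
#'
#' Fills the left and right 4x4 square windows with the given brightness
#' values; all other pixels are zero.
#'
#' @param x_left,x_right Brightness values in `[0, 1]`.
#' @return A 16x32 `saccadia_frame` with `attr(, "phase") == "stim"`.
#' @export
render_stimulus <- function(x_left, x_right) {
  if (x_left < 0 || x_left > 1 || x_right < 0 || x_right > 1)
    stop("brightness values must lie in [0, 1]")
  f <- .blank_frame("stim")
  f[.left_rows, .left_cols] <- x_left
  f[.right_rows, .right_cols] <- x_right
  f
}

.correct_side <- function(x_left, x_right, cue) {
  ifelse(x_left == x_right, "undefined",
         ifelse((x_left > x_right) == (cue == "pro"), "left", "right"))
}

#' Enumerate the training set of brightness pairs
#'
#' All ordered pairs of brightness values on the 11-point grid
#' \{0.0, 0.1, ..., 1.0\} (121 pairs). Each pair is tagged with the correct
#' saccade side under both cue rules; equal-brightness pairs carry an
#' `"undefined"` side and are excluded from side-classification training.
#' Grid values are generated as exact integer ratios i/10.
#'
#' @return A data frame with columns `x_left`, `x_right`, `difficulty`
#'   (`|x_left - x_right|`), `correct_pro`, `correct_anti`.
#' @export
make_training_set <- function() {
  g <- 0:10 / 10
  d <- expand.grid(x_left = g, x_right = g, KEEP.OUT.ATTRS = FALSE)
  d$difficulty <- abs(d$x_left - d$x_right)
  d$correct_pro <- .correct_side(d$x_left, d$x_right, "pro")
  d$correct_anti <- .correct_side(d$x_left, d$x_right, "anti")
  attr(d, "grid_interval") <- 0.1
  d
}

#' Sample a balanced test set of brightness pairs
#'
#' Pairs are drawn without replacement from the ten-fold finer 0.01-interval
#' grid (101 x 101 combinations, equal-brightness diagonal excluded), with
#' exactly `n/2` left-brighter and `n/2` right-brighter pairs.
#'
#' @param n Even number of pairs (default 1000).
#' @param seed Integer seed; the draw is reproducible.
#' @return A data frame like [make_training_set()], plus attribute
#'   `balanced = TRUE`.
#' @export
make_test_set <- function(n = 1000, seed = 1) {
  if (n %% 2 != 0) stop("n must be even for a balanced set")
  g <- 0:100
  cand <- expand.grid(i = g, j = g, KEEP.OUT.ATTRS = FALSE)
  cand <- cand[cand$i != cand$j, ]
  left <- cand[cand$i > cand$j, ]
  right <- cand[cand$i < cand$j, ]
  if (n / 2 > nrow(left)) stop("n exceeds the number of distinct pairs")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  pick <- rbind(left[sample.int(nrow(left), n / 2), ],
                right[sample.int(nrow(right), n / 2), ])
  pick <- pick[sample.int(nrow(pick)), ]
  d <- data.frame(x_left = pick$i / 100, x_right = pick$j / 100)
  d$difficulty <- abs(d$x_left - d$x_right)
  d$correct_pro <- .correct_side(d$x_left, d$x_right, "pro")
  d$correct_anti <- .correct_side(d$x_left, d$x_right, "anti")
  rownames(d) <- NULL
  attr(d, "grid_interval") <- 0.01
  attr(d, "balanced") <- TRUE
  d
}

#' Build trial specifications from brightness pairs
#'
#' Attaches a cue condition to each pair and resolves the correct side under
#' that cue.
#'
#' @param pairs Data frame from [make_training_set()] or [make_test_set()].
#' @param cue `"pro"`, `"anti"`, or a vector of length `nrow(pairs)`.
#' @return Data frame with columns `trial_id`, `cue`, `x_left`, `x_right`,
#'   `correct_side`, `difficulty`.
#' @export
as_trials <- function(pairs, cue) {
  cue <- rep(cue, length.out = nrow(pairs))
  stopifnot(all(cue %in% c("pro", "anti")))
  data.frame(trial_id = seq_len(nrow(pairs)), cue = cue,
             x_left = pairs$x_left, x_right = pairs$x_right,
             correct_side = .correct_side(pairs$x_left, pairs$x_right, cue),
             difficulty = pairs$difficulty)
}

#' Add Gaussian pixel noise to a frame
#'
#' Perturbs every pixel with an independent draw from `N(0, sigma)`. Noised
#' intensities are deliberately not clipped to `[0, 1]`. Uses the global R
#' random stream, so results are reproducible under [set.seed()].
#'
#' @param frame A `saccadia_frame`.
#' @param sigma Noise standard deviation (>= 0).
#' @return The noised frame (unchanged when `sigma == 0`).
#' @export
add_noise <- function(frame, sigma) {
  if (sigma < 0) stop("sigma must be nonnegative")
  if (sigma == 0) return(frame)
  frame + stats::rnorm(length(frame), 0, sigma)
}

#' Write a frame as CSV of pixel values
#' @param frame A `saccadia_frame`.
#' @param path Output file path.
#' @export
write_frame_csv <- function(frame, path) {
  utils::write.table(unclass(frame), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a trial table as CSV
#' @param trials Data frame from [as_trials()] or a result table.
#' @param path Output file path.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

## Save/restore the global RNG state so seeded helpers do not clobber the
## caller's stream.
.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
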