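#' Eccentricity levels of the annulus display
#'
#' The three annulus eccentricities used to manipulate attentional breadth,
#' with their radii in degrees of visual angle and the ordinal codes used by
#' every statistical model in the package (-1 = near, 0 = medium, +1 = far).
#'
#' @return A data.frame with columns `label`, `radius_deg`, `ordinal_code`.
#' @export
eccentricity_table <- function() {
  data.frame(
    label = c("near", "medium", "far"),
    radius_deg = c(1.16, 3.47, 10.40),
    ordinal_code = c(-1L, 0L, 1L),
    stringsAsFactors = FALSE
  )
}

ECC_LABELS <- c("near", "medium", "far")
LOC_LABELS <- c("up", "down", "left", "right")
EXP1_SYMBOLS <- c("□", "○", "◁") # square, circle, triangle
VARIANTS <- c("exp1", "exp2", "exp3")

#' Map eccentricity labels to ordinal codes
#'
#' @param label character vector of `"near"`, `"medium"`, `"far"`.
#' @return Integer vector of codes in \{-1, 0, 1\}.
#' @export
ecc_code <- function(label) {
  code <- c(near = -1L, medium = 0L, far = 1L)[label]
  if (anyNA(code)) stop("unknown eccentricity label(s): ",
                        paste(unique(label[is.na(code)]), collapse = ", "))
  unname(code)
}

participant_index <- function(participant_id) {
  stopifnot(is.character(participant_id), nzchar(participant_id))
  digits <- gsub("\\D", "", participant_id)
  if (nzchar(digits)) as.integer(substr(digits, 1, 9)) else
    sum(utf8ToInt(participant_id))
}

# the 6 permutations of near/medium/far, fixed lexicographic order
ECC_PERMS <- matrix(c(
  "near", "medium", "far",
  "near", "far", "medium",
  "medium", "near", "far",
  "medium", "far", "near",
  "far", "near", "medium",
  "far", "medium", "near"
), ncol = 3, byrow = TRUE)

#' Counterbalanced cue-symbol mapping
#'
#' For the symbolic-cue variant (`exp1`) the three cue symbols (square,
#' circle, triangle) are assigned to the three eccentricities as one of the 6
#' permutations, chosen deterministically from the participant's numeric
#' index so that across any 6 consecutive participant indices each permutation
#' occurs exactly once. For `exp2` and the location condition of `exp3` the
#' mapping is the fixed code scheme: digits 1/2/3 denote the near/medium/far
#' annulus and letters U/D/R/L the up/down/right/left location (a cue such as
#' `"U2"` therefore denotes the upper location of the middle annulus).
#'
#' @param participant_id non-empty participant identifier; a trailing or
#'   embedded number (e.g. `"p07"`) is used as the counterbalancing index.
#' @param variant `"exp1"`, `"exp2"` or `"exp3"`.
#' @return A list with elements `ecc` (named character vector, cue symbol ->
#'   eccentricity label) and `loc` (named vector, letter -> location; `NULL`
#'   for `exp1`).
#' @export
counterbalance_symbol_mapping <- function(participant_id, variant = "exp1") {
  variant <- match.arg(variant, VARIANTS)
  if (variant == "exp1") {
    idx <- participant_index(participant_id)
    perm <- ECC_PERMS[(idx - 1L) %% 6L + 1L, ]
    list(ecc = stats::setNames(perm, EXP1_SYMBOLS), loc = NULL)
  } else {
    list(ecc = stats::setNames(ECC_LABELS, c("1", "2", "3")),
         loc = stats::setNames(c("up", "down", "right", "left"),
                               c("U", "D", "R", "L")))
  }
}

#' Parse a combined location-eccentricity cue code
#'
#' @param cue cue string such as `"U2"` (letter = location, digit = annulus).
#' @param mapping mapping list from [counterbalance_symbol_mapping()].
#' @return list with `ecc` and `loc` labels.
#' @export
parse_cue <- function(cue, mapping = counterbalance_symbol_mapping("p01", "exp2")) {
  letter <- gsub("[0-9]", "", cue)
  digit <- gsub("[^0-9]", "", cue)
  if (!letter %in% names(mapping$loc) || !digit %in% names(mapping$ecc))
    stop("cannot parse cue code: ", cue)
  list(ecc = unname(mapping$ecc[digit]), loc = unname(mapping$loc[letter]))
}

#' Draw target onsets within the late noise window
#'
#' The target can appear at any moment within the final second of the dynamic
#' noise display; onsets are drawn uniformly on \[3000, 4000) ms after cue
#' onset (the noise display runs for 3000 ms before the target window opens,
#' so 3000 ms is the earliest possible target onset).
#'
#' @param n number of draws.
#' @return numeric vector of onsets in ms post cue onset.
#' @export
sample_target_onset <- function(n = 1) {
  stats::runif(n, 3000, 4000)
}

# per-cell trial construction for one phase (or one exp3 breadth type).
# Validity is enforced exactly per cued eccentricity (80/20); invalid targets
# are spread uniformly over non-cued eccentricities (size condition) or
# non-cued annulus/location combinations (location condition); target polarity
# alternates 50/50 within each cell.
build_trial_pool <- function(n_total, breadth_type, prop_valid = 0.8) {
  if (breadth_type == "size") {
    cells <- data.frame(cued_ecc = ECC_LABELS, cued_loc = "none",
                        stringsAsFactors = FALSE)
  } else {
    cells <- expand.grid(cued_loc = LOC_LABELS, cued_ecc = ECC_LABELS,
                         stringsAsFactors = FALSE)[, c("cued_ecc", "cued_loc")]
  }
  n_ecc <- apportion(n_total, rep(1, length(ECC_LABELS)))
  rows <- vector("list", nrow(cells))
  for (e in seq_along(ECC_LABELS)) {
    ecc <- ECC_LABELS[e]
    sub <- which(cells$cued_ecc == ecc)
    n_cell <- apportion(n_ecc[e], rep(1, length(sub)))
    n_valid_cell <- apportion(round(prop_valid * n_ecc[e]), n_cell)
    for (j in seq_along(sub)) {
      cell <- cells[sub[j], ]
      nv <- n_valid_cell[j]
      ni <- n_cell[j] - nv
      validity <- c(rep("valid", nv), rep("invalid", ni))
      target_ecc <- rep(cell$cued_ecc, n_cell[j])
      target_loc <- if (breadth_type == "size")
        sample(LOC_LABELS, n_cell[j], replace = TRUE)
      else rep(cell$cued_loc, n_cell[j])
      if (ni > 0) {
        inv <- which(validity == "invalid")
        if (breadth_type == "size") {
          target_ecc[inv] <- sample(setdiff(ECC_LABELS, cell$cued_ecc),
                                    ni, replace = TRUE)
        } else {
          others <- expand.grid(loc = LOC_LABELS, ecc = ECC_LABELS,
                                stringsAsFactors = FALSE)
          others <- others[!(others$ecc == cell$cued_ecc &
                             others$loc == cell$cued_loc), ]
          pick <- others[sample(nrow(others), ni, replace = TRUE), ]
          target_ecc[inv] <- pick$ecc
          target_loc[inv] <- pick$loc
        }
      }
      rows[[sub[j]]] <- data.frame(
        breadth_type = breadth_type,
        cued_ecc = cell$cued_ecc, cued_loc = cell$cued_loc,
        validity = validity, target_ecc = target_ecc, target_loc = target_loc,
        target_polarity = sample(rep(c("increment", "decrement"),
                                     length.out = n_cell[j])),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Build a complete, reproducible session design
#'
#' Generates the full trial-by-trial schedule for one participant in one of
#' the three experiment variants: 330 trials in 10 equal blocks, with 90
#' practice + 240 experimental trials (`exp1`, `exp2`) or 30 practice + 300
#' experimental trials (`exp3`, split 150/150 between the location and size
#' conditions, each occupying 5 contiguous blocks whose order is
#' counterbalanced across participants). Experimental trials are exactly 80%
#' valid within each cued eccentricity, cued eccentricities are balanced, and
#' the schedule is fully determined by `(variant, participant_id, seed)`.
#' Practice trials mirror the experimental proportions and open each block.
#'
#' @param variant `"exp1"` (symbolic size cues), `"exp2"` (location cues) or
#'   `"exp3"` (both, blocked).
#' @param participant_id non-empty identifier; its numeric index drives
#'   counterbalancing of the symbol mapping and (exp3) block order.
#' @param seed non-negative integer master seed.
#' @return An object of class `session_design`: a list with
#'   `participant_id`, `variant`, `symbol_mapping`, `trials` (data.frame, one
#'   row per trial) and `seed`.
#' @examples
#' d <- build_session("exp1", "p01", seed = 1)
#' table(d$trials$phase)
#' @export
build_session <- function(variant, participant_id, seed) {
  if (!is.character(variant) || length(variant) != 1 || !variant %in% VARIANTS)
    stop("unknown variant '", paste(variant, collapse = ","),
         "'; valid variants are: ", paste(VARIANTS, collapse = ", "))
  stopifnot(is.character(participant_id), nzchar(participant_id),
            is.numeric(seed), seed >= 0)
  set.seed(substream_seed(seed, paste("design", variant, participant_id)))

  n_blocks <- 10L
  if (variant %in% c("exp1", "exp2")) {
    breadth <- if (variant == "exp1") "size" else "location"
    prac <- build_trial_pool(90L, breadth)
    expe <- build_trial_pool(240L, breadth)
    prac_blocks <- split_into_blocks(prac, n_blocks)
    expe_blocks <- split_into_blocks(expe, n_blocks)
  } else {
    idx <- participant_index(participant_id)
    first <- if (idx %% 2L == 1L) "location" else "size"
    second <- setdiff(c("location", "size"), first)
    prac1 <- build_trial_pool(15L, first); expe1 <- build_trial_pool(150L, first)
    prac2 <- build_trial_pool(15L, second); expe2 <- build_trial_pool(150L, second)
    prac_blocks <- c(split_into_blocks(prac1, 5L), split_into_blocks(prac2, 5L))
    expe_blocks <- c(split_into_blocks(expe1, 5L), split_into_blocks(expe2, 5L))
  }

  blocks <- lapply(seq_len(n_blocks), function(b) {
    pb <- prac_blocks[[b]]; eb <- expe_blocks[[b]]
    pb$phase <- "practice"; eb$phase <- "experimental"
    out <- rbind(pb, eb)
    out$block <- b
    out
  })
  trials <- do.call(rbind, blocks)
  trials$trial_index <- seq_len(nrow(trials))
  trials$target_onset_ms <- sample_target_onset(nrow(trials))
  trials$cue_duration_ms <- 1000
  trials$target_duration_ms <- 30
  trials$post_target_noise_ms <- 300
  trials <- trials[, c("trial_index", "block", "phase", "breadth_type",
                       "cued_ecc", "cued_loc", "validity", "target_ecc",
                       "target_loc", "target_polarity", "target_onset_ms",
                       "cue_duration_ms", "target_duration_ms",
                       "post_target_noise_ms")]
  rownames(trials) <- NULL
  structure(list(participant_id = participant_id, variant = variant,
                 symbol_mapping = counterbalance_symbol_mapping(participant_id,
                                                                variant),
                 trials = trials, seed = seed),
            class = "session_design")
}

# shuffle a trial pool and divide it into n equal consecutive blocks
split_into_blocks <- function(pool, n_blocks) {
  stopifnot(nrow(pool) %% n_blocks == 0)
  pool <- pool[sample(nrow(pool)), , drop = FALSE]
  per <- nrow(pool) / n_blocks
  lapply(seq_len(n_blocks), function(b)
    pool[((b - 1) * per + 1):(b * per), , drop = FALSE])
}

#' @export
print.session_design <- function(x, ...) {
  tab <- table(x$trials$phase)
  cat(sprintf("Session design: %s, participant %s, seed %d\n", x$variant,
              x$participant_id, x$seed))
  cat(sprintf("  %d trials in %d blocks (%d practice, %d experimental)\n",
              nrow(x$trials), max(x$trials$block),
              tab[["practice"]], tab[["experimental"]]))
  pv <- mean(x$trials$validity[x$trials$phase == "experimental"] == "valid")
  cat(sprintf("  experimental validity: %.0f%% valid\n", 100 * pv))
  invisible(x)
}

#' Serialize a session design to CSV
#'
#' One row per trial, columns exactly the trial-schedule fields, UTF-8,
#' comma-separated, with a header row.
#'
#' @param design a `session_design`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "session_design"))
  utils::write.csv(design$trials, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a serialized session design table
#'
#' @param path CSV written by [write_design()].
#' @return data.frame of trials.
#' @export
read_design <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
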