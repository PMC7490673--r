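# Data splitting: nonoverlapping day blocks, routing of DRH-only blocks
# into the healthy train/validation sets (H_R, H_CV), pooling of
# NR30-containing and leftover relapse-participant blocks (N_pool), and
# the stratified Monte Carlo partition of N_pool into N_CV and N_T.

#' Split each participant's day sequence into nonoverlapping blocks
#'
#' Consecutive, equal-length blocks of days. A short final remainder
#' becomes its own block but is anchored to the participant's final full
#' block: at assignment time it always follows that block's set, so no
#' temporal fragment is orphaned.
#'
#' @param day_labels data.table (participant_id, date, label) with
#'   labels in DRH/NR30/relapse. The relapse day itself belongs to no
#'   evaluation set and is excluded from the label counts.
#' @param block_len_days Block length in days (default 5).
#' @return data.table of blocks: participant_id, block_id, start_date,
#'   end_date, n_days, n_nr30, n_drh, has_nr30, remainder, anchor_block.
#' @export
make_blocks <- function(day_labels, block_len_days = 5) {
  assert_that(block_len_days >= 1, "block_len_days must be >= 1")
  dl <- data.table::as.data.table(day_labels)
  setkey(dl, participant_id, date)
  blocks <- dl[, {
    nd <- .N
    if (nd < block_len_days) {
      warning("participant ", participant_id[1], " has fewer days (", nd,
              ") than one block; emitting a single short block")
    }
    bid <- (seq_len(nd) - 1L) %/% block_len_days + 1L
    .(block_id = unique(bid),
      start_date = as.Date(tapply(date, bid, min), origin = "1970-01-01"),
      end_date = as.Date(tapply(date, bid, max), origin = "1970-01-01"),
      n_days = as.integer(table(bid)),
      n_nr30 = as.integer(tapply(label == "NR30", bid, sum)),
      n_drh = as.integer(tapply(label == "DRH", bid, sum)))
  }, by = participant_id]
  blocks[, has_nr30 := n_nr30 > 0]
  blocks[, remainder := n_days < block_len_days & block_id == max(block_id),
         by = participant_id]
  blocks[, anchor_block := ifelse(remainder & block_id > 1L,
                                  block_id - 1L, block_id)]
  blocks[]
}

#' Route blocks into H_R, H_CV and N_pool
#'
#' Nonrelapse participants' blocks all go to the healthy sets, split
#' 80/20 between H_R and H_CV. For relapse participants,
#' `pct_drh_in_train` percent of their DRH-only blocks are sampled into
#' the healthy sets (then 80/20); every block containing an NR30 day, and
#' every unsampled DRH block, goes to N_pool. The healthy sets therefore
#' contain zero NR30 days by construction, asserted on every run.
#'
#' @param blocks Output of [make_blocks()].
#' @param relapse_ids Character vector of relapse participants.
#' @param pct_drh_in_train One of 0, 20, 40, 60, 80 (the sweep grid);
#'   other values rejected unless `allow_any_pct = TRUE`.
#' @param seed Integer seed.
#' @param hcv_frac Fraction of healthy blocks routed to H_CV (default 0.2).
#' @param allow_any_pct Permit percentages outside the sweep grid.
#' @return Object of class `sw_splits`: the block table with a `set`
#'   column in {H_R, H_CV, N_pool}, plus attributes.
#' @export
assign_splits <- function(blocks, relapse_ids, pct_drh_in_train, seed = 1L,
                          hcv_frac = 0.2, allow_any_pct = FALSE) {
  if (!pct_drh_in_train %in% c(0, 20, 40, 60, 80) && !allow_any_pct) {
    stop("pct_drh_in_train must be one of 0, 20, 40, 60, 80 ",
         "(use allow_any_pct = TRUE to override)", call. = FALSE)
  }
  bl <- data.table::copy(data.table::as.data.table(blocks))
  bl[, set := NA_character_]
  with_seed(seed, {
    for (pid in unique(bl$participant_id)) {
      rows <- which(bl$participant_id == pid & !bl$remainder)
      if (pid %in% relapse_ids) {
        nr_rows <- rows[bl$has_nr30[rows]]
        drh_rows <- rows[!bl$has_nr30[rows]]
        bl$set[nr_rows] <- "N_pool"
        n_h <- round(length(drh_rows) * pct_drh_in_train / 100)
        to_h <- if (n_h > 0) sample(drh_rows, n_h) else integer(0)
        bl$set[setdiff(drh_rows, to_h)] <- "N_pool"
        if (length(to_h)) {
          n_cv <- round(length(to_h) * hcv_frac)
          to_cv <- if (n_cv > 0) sample(to_h, n_cv) else integer(0)
          bl$set[to_cv] <- "H_CV"
          bl$set[setdiff(to_h, to_cv)] <- "H_R"
        }
      } else {
        n_cv <- round(length(rows) * hcv_frac)
        to_cv <- if (n_cv > 0) sample(rows, n_cv) else integer(0)
        bl$set[to_cv] <- "H_CV"
        bl$set[setdiff(rows, to_cv)] <- "H_R"
      }
    }
  })
  # remainder blocks follow their anchor block's assignment
  rem <- which(bl$remainder & is.na(bl$set))
  if (length(rem)) {
    key <- paste(bl$participant_id, bl$block_id)
    bl$set[rem] <- bl$set[match(paste(bl$participant_id[rem],
                                      bl$anchor_block[rem]), key)]
  }
  # nonrelapse participants with NR30 blocks would be a labeling bug
  assert_that(all(bl$n_nr30[bl$set %in% c("H_R", "H_CV")] == 0),
              "label purity violated: NR30 days routed to an H set")
  structure(bl[], class = c("sw_splits", class(bl)),
            pct_drh_in_train = pct_drh_in_train, seed = seed)
}

#' Stratified Monte Carlo partition of N_pool into N_CV and N_T
#'
#' Per relapse participant, NR30-containing blocks are divided so that
#' the NR30 day counts on the two sides differ by at most one block;
#' DRH-only blocks in N_pool are split 50/50. A participant with a
#' single NR30 block alternates sides across iterations (with a
#' warning). Deterministic in (base_seed, iteration).
#'
#' @param splits An `sw_splits` from [assign_splits()].
#' @param iteration Monte Carlo iteration number (1-based).
#' @param base_seed Integer base seed.
#' @return The block table with set values H_R/H_CV/N_CV/N_T.
#' @export
monte_carlo_partition <- function(splits, iteration, base_seed = 1L) {
  bl <- data.table::copy(data.table::as.data.table(splits))
  pool <- which(bl$set == "N_pool")
  assert_that(length(pool) > 0, "N_pool is empty")
  seed <- derive_seed(base_seed, iteration)
  with_seed(seed, {
    for (pid in unique(bl$participant_id[pool])) {
      rows <- pool[bl$participant_id[pool] == pid]
      nr_rows <- rows[bl$has_nr30[rows]]
      drh_rows <- rows[!bl$has_nr30[rows]]
      if (length(nr_rows) == 1L) {
        warning("participant ", pid, " has a single NR30 block; ",
                "alternating assignment across iterations")
        side <- if (iteration %% 2L == 1L) "N_CV" else "N_T"
        bl$set[nr_rows] <- side
      } else if (length(nr_rows) > 1L) {
        # greedy balance of NR30 day counts over a shuffled order
        ord <- sample(nr_rows)
        ncv_days <- 0L
        nt_days <- 0L
        for (r in ord) {
          if (ncv_days <= nt_days) {
            bl$set[r] <- "N_CV"
            ncv_days <- ncv_days + bl$n_nr30[r]
          } else {
            bl$set[r] <- "N_T"
            nt_days <- nt_days + bl$n_nr30[r]
          }
        }
      }
      if (length(drh_rows)) {
        half <- sample(drh_rows, floor(length(drh_rows) / 2))
        bl$set[half] <- "N_CV"
        bl$set[setdiff(drh_rows, half)] <- "N_T"
      }
    }
  })
  # remainder blocks that anchored into N_pool follow their anchor
  rem <- which(bl$remainder & bl$set == "N_pool")
  if (length(rem)) {
    key <- paste(bl$participant_id, bl$block_id)
    bl$set[rem] <- bl$set[match(paste(bl$participant_id[rem],
                                      bl$anchor_block[rem]), key)]
  }
  bl[]
}

#' Serialize a block-to-set assignment as a JSON manifest
#'
#' @param splits An `sw_splits` (or partitioned block table).
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
write_split_manifest <- function(splits, path) {
  bl <- data.table::as.data.table(splits)
  manifest <- list(
    pct_drh_in_train = attr(splits, "pct_drh_in_train"),
    seed = attr(splits, "seed"),
    blocks = bl[, .(participant_id, block_id,
                    start_date = format(start_date),
                    end_date = format(end_date), n_days, n_nr30, set)])
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}

# Map participant-days to their split set for one iteration.
day_assignment <- function(blocks, day_labels) {
  dl <- data.table::as.data.table(day_labels)
  bl <- data.table::as.data.table(blocks)
  out <- bl[, .(participant_id, start_date, end_date, set)][
    dl, on = .(participant_id, start_date <= date, end_date >= date),
    .(participant_id = i.participant_id, date = i.date, label = i.label,
      set = x.set)]
  out[label == "relapse", set := NA_character_]
  out[]
}
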