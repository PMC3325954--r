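# Shared fixture builders; everything is generated in code at test time.

tiny_matrix <- function() {
  vals <- matrix(c(8.0, 8.2, 8.4, 7.0, 7.2, 7.4, 6.9, 7.1, 7.0,
                   5.0, 5.1, 4.9, 5.0, 5.2, 5.1, 5.0, 5.1, 5.2,
                   9.0, 9.1, 8.9, 9.2, 9.0, 9.1, 8.8, 9.0, 9.2),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(paste0("p", 1:3),
                                 c(paste0("null_r", 1:3), paste0("P3_r", 1:3),
                                   paste0("P5_r", 1:3))))
  design <- data.frame(sample_id = colnames(vals),
                       condition = rep(c("null", "P3", "P5"), each = 3),
                       replicate = rep(1:3, 3), stringsAsFactors = FALSE)
  expression_matrix(vals, design)
}

# signature over a universe, by explicit members
sig <- function(ids, dirs, universe = paste0("p", 1:1000)) {
  significant_set(ids, dirs, universe = universe)
}

# paired-direction signatures whose directional_overlap reproduces given
# quadrant counts (uu, ud, du, dd) plus optional set-only members
sig_pair_from_quadrants <- function(uu, ud, du, dd,
                                    a_only_up = 0, a_only_down = 0,
                                    b_only_up = 0, b_only_down = 0) {
  n <- uu + ud + du + dd
  total <- n + a_only_up + a_only_down + b_only_up + b_only_down
  ids <- sprintf("probe_%04d", seq_len(total))
  shared <- ids[seq_len(n)]
  da <- rep(c(1L, 1L, -1L, -1L), c(uu, ud, du, dd))
  db <- rep(c(1L, -1L, 1L, -1L), c(uu, ud, du, dd))
  a_ids <- c(shared, ids[n + seq_len(a_only_up + a_only_down)])
  a_dir <- c(da, rep(c(1L, -1L), c(a_only_up, a_only_down)))
  b_extra <- ids[n + a_only_up + a_only_down + seq_len(b_only_up + b_only_down)]
  b_ids <- c(shared, b_extra)
  b_dir <- c(db, rep(c(1L, -1L), c(b_only_up, b_only_down)))
  list(a = significant_set(a_ids, a_dir, universe = ids),
       b = significant_set(b_ids, b_dir, universe = ids))
}
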