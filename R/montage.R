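#' The eight-channel equine EEG montage
#'
#' Two rows of four electrodes, one row per hemisphere, covering the frontal,
#' temporal, parietal and occipital regions. Channel numbering runs down the
#' right hemisphere from frontal to occipital (1-4) and back up the left
#' hemisphere from occipital to frontal (5-8), so channels 4 and 5 are the
#' two occipital electrodes.
#'
#' @return A data frame of class `montage` with columns `channel` (1-8),
#'   `hemisphere` (`"right"`/`"left"`), `region` and `label` (e.g. `"fr"` for
#'   frontal right).
#' @export
#' @examples
#' horse_montage()
horse_montage <- function() {
  m <- data.frame(
    channel = 1:8,
    hemisphere = c(rep("right", 4), rep("left", 4)),
    region = c("frontal", "temporal", "parietal", "occipital",
               "occipital", "parietal", "temporal", "frontal"),
    label = c("fr", "tr", "pr", "or", "ol", "pl", "tl", "fl"),
    stringsAsFactors = FALSE
  )
  class(m) <- c("montage", "data.frame")
  m
}

# anterior-posterior rank used to grade electrode distance
.region_rank <- c(frontal = 1, temporal = 2, parietal = 3, occipital = 4)

#' @rdname horse_montage
#' @param montage A montage data frame.
#' @export
validate_montage <- function(montage) {
  stopifnot(is.data.frame(montage),
            all(c("channel", "hemisphere", "region", "label") %in% names(montage)))
  if (nrow(montage) != 8L || !identical(as.integer(montage$channel), 1:8))
    stop("montage must have exactly 8 channels indexed 1..8")
  combo <- paste(montage$hemisphere, montage$region)
  if (anyDuplicated(combo))
    stop("each (hemisphere, region) combination must occur exactly once")
  if (!all(montage$hemisphere %in% c("right", "left")) ||
      !all(montage$region %in% names(.region_rank)))
    stop("unknown hemisphere or region in montage")
  invisible(montage)
}

#' Canonical enumeration of the 28 electrode pairs
#'
#' All unordered channel pairs in lexicographic order on
#' (smaller index, larger index), i.e. (1,2) = 1, (1,3) = 2, ..., (7,8) = 28.
#' Pair 19 is the occipital right/left pair (channels 4 and 5) and pair 9 the
#' temporal right/occipital right pair (channels 2 and 4).
#'
#' @param montage A montage, by default [horse_montage()].
#' @return Data frame with columns `pair_index`, `channel_a`, `channel_b`
#'   (`channel_a < channel_b`) and `abbreviation` (e.g. `"or/ol"`).
#' @export
#' @examples
#' build_pair_table()[19, ]
build_pair_table <- function(montage = horse_montage()) {
  validate_montage(montage)
  cmb <- utils::combn(8L, 2L)
  data.frame(
    pair_index = seq_len(ncol(cmb)),
    channel_a = cmb[1L, ],
    channel_b = cmb[2L, ],
    abbreviation = paste(montage$label[cmb[1L, ]], montage$label[cmb[2L, ]],
                         sep = "/"),
    stringsAsFactors = FALSE
  )
}

#' Assign an electrode pair to its spatial group
#'
#' Interhemispheric pairs form the horizontal groups H1-H4 and intrahemispheric
#' pairs the vertical groups V1-V3. The group number grows with the
#' anterior-posterior distance between the two regions (the "diagonal grade"):
#' directly opposite electrodes are H1, a grade-one diagonal such as frontal
#' right/temporal left is H2, and so on; within a hemisphere adjacent regions
#' are V1 and the full frontal-occipital span is V3.
#'
#' @param channel_a,channel_b Channel indices (1-8); order is irrelevant.
#' @param montage A montage.
#' @return A group label, one of `"H1".."H4"`, `"V1".."V3"`.
#' @export
#' @examples
#' assign_group(4, 5)  # occipital right vs left -> "H1"
#' assign_group(1, 2)  # frontal right vs temporal right -> "V1"
assign_group <- function(channel_a, channel_b, montage = horse_montage()) {
  validate_montage(montage)
  a <- as.integer(channel_a); b <- as.integer(channel_b)
  if (length(a) != 1L || length(b) != 1L || is.na(a) || is.na(b) ||
      !a %in% montage$channel || !b %in% montage$channel)
    stop("channel indices must each be a single value in 1..8")
  if (a == b) stop("invalid pair: the two channels must differ")
  grade <- abs(.region_rank[[montage$region[a]]] -
               .region_rank[[montage$region[b]]])
  if (montage$hemisphere[a] == montage$hemisphere[b])
    paste0("V", grade)
  else
    paste0("H", grade + 1L)
}

#' Pair table with spatial group assignment
#'
#' @inheritParams build_pair_table
#' @return The pair table of [build_pair_table()] with an extra `group`
#'   column. The seven groups partition the 28 pairs with sizes
#'   H1=4, H2=6, H3=4, H4=2, V1=6, V2=4, V3=2.
#' @export
group_scheme <- function(montage = horse_montage()) {
  pt <- build_pair_table(montage)
  pt$group <- vapply(seq_len(nrow(pt)), function(i)
    assign_group(pt$channel_a[i], pt$channel_b[i], montage), character(1))
  pt
}

#' Sizes of the seven electrode groups
#'
#' @inheritParams build_pair_table
#' @return Named integer vector over H1..H4, V1..V3.
#' @export
group_sizes <- function(montage = horse_montage()) {
  sc <- group_scheme(montage)
  tab <- table(factor(sc$group, levels = c("H1", "H2", "H3", "H4",
                                           "V1", "V2", "V3")))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Export the pair table and group scheme for audit
#'
#' Writes a tab-separated file with columns pair_index, channel_a, channel_b,
#' abbreviation and group.
#'
#' @param path Output file path.
#' @inheritParams build_pair_table
#' @return The path, invisibly.
#' @export
write_group_scheme <- function(path, montage = horse_montage()) {
  write.table(group_scheme(montage), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
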