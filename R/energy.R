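#' Nearest-neighbor duplex energy table
#'
#' A reduced RNA-RNA hybridization model: Watson-Crick stack increments from
#' the Turner nearest-neighbor set (delta-G at 37 C, kcal/mol), a uniform
#' increment for wobble-containing stacks, a duplex initiation penalty, a
#' terminal A:U / G:U closing penalty per duplex end, and affine penalties
#' for internal loops/bulges (each maximal run of unpaired internal columns
#' costs `loop_open` plus `loop_extend` per additional column). The model
#' scores duplex hybridization only; intramolecular folding of either strand
#' is not modelled.
#'
#' Stack keys are written `TT/MM`: two adjacent target bases 5'->3' over the
#' two miRNA bases aligned to them (miRNA read 3'->5'), i.e. the two aligned
#' columns left to right.
#'
#' @param wobble_stack Increment (kcal/mol) for any stack containing a G:U
#'   pair.
#' @param initiation Duplex initiation penalty.
#' @param terminal_au Penalty per duplex end closed by A:U or G:U.
#' @param loop_open,loop_extend Internal loop/bulge penalties.
#' @return An `nn_energy_table` list.
#' @export
nn_energy_table <- function(wobble_stack = -0.5, initiation = 4.09,
                            terminal_au = 0.45, loop_open = 3.9,
                            loop_extend = 0.3) {
  base <- c("AA/UU" = -0.93, "AU/UA" = -1.10, "UA/AU" = -1.33,
            "CU/GA" = -2.08, "CA/GU" = -2.11, "GU/CA" = -2.24,
            "GA/CU" = -2.35, "CG/GC" = -2.36, "GG/CC" = -3.26,
            "GC/CG" = -3.42)
  stacks <- base
  # rotational symmetry: 5'XY3'/3'WZ5' reads identically as 5'ZW3'/3'YX5'
  for (k in names(base)) {
    t <- strsplit(substr(k, 1, 2), "")[[1]]
    m <- strsplit(substr(k, 4, 5), "")[[1]]
    rot <- paste0(m[2], m[1], "/", t[2], t[1])
    if (!rot %in% names(stacks)) stacks[rot] <- base[[k]]
  }
  assert_that(all(stacks < 0), "stack increments must be negative")
  assert_that(wobble_stack < 0, "wobble stack increment must be negative")
  assert_that(initiation >= 0 && terminal_au >= 0 && loop_open >= 0 &&
                loop_extend >= 0, "penalties must be non-negative")
  structure(list(stacks = stacks, wobble_stack = wobble_stack,
                 initiation = initiation, terminal_au = terminal_au,
                 loop_open = loop_open, loop_extend = loop_extend),
            class = "nn_energy_table")
}

#' Duplex hybridization free energy of an alignment
#'
#' Sums nearest-neighbor stack increments over consecutive paired columns,
#' plus the initiation penalty, terminal A:U/G:U penalties, and affine
#' internal loop/bulge penalties for every maximal run of unpaired columns
#' between paired columns. Lower (more negative) is more stable.
#'
#' @param alignment A `duplex_alignment` from [align_duplex()].
#' @param table An [nn_energy_table()].
#' @return Free energy estimate in kcal/mol.
#' @export
duplex_energy <- function(alignment, table = nn_energy_table()) {
  pairs <- strsplit(alignment$pair_line, "")[[1]]
  paired <- which(pairs %in% c("|", ":"))
  if (!length(paired)) {
    stop("duplex energy undefined: alignment has no paired columns",
         call. = FALSE)
  }
  m <- strsplit(alignment$mirna_aln, "")[[1]]
  t <- strsplit(alignment$target_aln, "")[[1]]
  dg <- table$initiation
  # stacks and internal loops between consecutive paired columns
  for (k in seq_len(length(paired) - 1L)) {
    i <- paired[k]; j <- paired[k + 1L]
    if (j == i + 1L) {
      key <- paste0(t[i], t[j], "/", m[i], m[j])
      if (key %in% names(table$stacks)) {
        dg <- dg + table$stacks[[key]]
      } else {
        dg <- dg + table$wobble_stack
      }
    } else {
      gap <- j - i - 1L
      dg <- dg + table$loop_open + table$loop_extend * (gap - 1L)
    }
  }
  # terminal closing-pair penalties at both duplex ends
  for (i in c(paired[1], paired[length(paired)])) {
    if (pairs[i] == ":" || t[i] %in% c("A", "U")) dg <- dg + table$terminal_au
  }
  unname(dg)
}
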