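## Nearest-neighbor RNA/RNA duplex thermodynamics at 37 degC. Stacking free
## energies (kcal/mol) for all Watson-Crick and G.U wobble nearest-neighbor
## stacks from the Turner 2004 parameter set (WC values are the Xia et al.
## 1998 measurements to 0.1 kcal/mol, e.g. 5'GC/3'CG = -3.40,
## 5'AA/3'UU = -0.90), plus the duplex initiation penalty (+4.09) and the
## terminal AU/GU end penalty (+0.45).

## Pair order used for both matrix dimensions.
NN_PAIRS <- c("CG", "GC", "GU", "UG", "AU", "UA")

## stack_matrix[p1, p2] is the free energy of the stack
##   5'-X Y-3'
##   3'-Z W-5'
## with p1 = XZ (outer pair, read top-to-bottom) and p2 = WY (inner pair,
## read bottom-to-top).
NN_STACK <- matrix(c(
  -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,   # CG
  -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,   # GC
  -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,   # GU
  -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,   # UG
  -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,   # AU
  -2.10, -2.40, -1.30, -1.00, -0.90, -1.30    # UA
), nrow = 6, byrow = TRUE, dimnames = list(NN_PAIRS, NN_PAIRS))

#' Nearest-neighbor duplex parameter table
#'
#' Returns the bundled nearest-neighbor free-energy parameters used by
#' [duplex_free_energy()]: Turner 2004 RNA/RNA stacking free energies at
#' 37 degC covering all Watson-Crick and G.U wobble stacks, a duplex
#' initiation penalty, and a terminal AU/GU end penalty. Mismatches
#' contribute no stabilisation under this model (stacks are broken across
#' them), a deliberately conservative simplification relative to full
#' internal-loop models.
#'
#' @param init_penalty duplex initiation free energy (default +4.09).
#' @param au_end_penalty per-end penalty for a terminal AU or GU pair
#'   (default +0.45).
#' @return list of class `nn_params` with `stack_energies` (6 x 6 matrix in
#'   kcal/mol over pairs CG/GC/GU/UG/AU/UA), `init_penalty`,
#'   `au_end_penalty`.
#' @export
nn_params <- function(init_penalty = 4.09, au_end_penalty = 0.45) {
  structure(list(stack_energies = NN_STACK, init_penalty = init_penalty,
                 au_end_penalty = au_end_penalty),
            class = "nn_params")
}

#' @export
print.nn_params <- function(x, ...) {
  cat("Nearest-neighbor RNA duplex parameters (37 degC, kcal/mol)\n")
  cat("  initiation:", x$init_penalty, "; terminal AU/GU:", x$au_end_penalty, "\n")
  print(x$stack_energies)
  invisible(x)
}

## Pair label for bases a (top) and b (bottom), RNA letters; NA if a and b
## are neither Watson-Crick nor wobble.
pair_label <- function(a, b) {
  key <- paste0(a, b)
  ifelse(key %in% NN_PAIRS, key, NA_character_)
}

## Stack free energy for 5'x1 x2/3'z1 z2 (x1:z1 and x2:z2 both paired).
stack_energy <- function(params, x1, x2, z1, z2) {
  p1 <- pair_label(x1, z1)
  p2 <- pair_label(z2, x2)
  if (is.na(p1) || is.na(p2)) {
    stop("unknown nearest-neighbor dinucleotide pair: 5'", x1, x2, "/3'",
         z1, z2, call. = FALSE)
  }
  params$stack_energies[p1, p2]
}
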