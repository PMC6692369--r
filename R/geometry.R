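#' Spliceosomal B-complex geometry model
#'
#' Geometric parameters of the pre-catalytic (B) spliceosome that constrain
#' how short an intron's 5' splice-site-to-branch-site span can be: the
#' intron forms an extended helix with U6 at the 5'SS and a helix with U2 at
#' the BS, and the two helices sit a fixed distance apart in the complex.
#'
#' @param helix_5ss_nt Intron nucleotides locked in the U6/5'SS extended
#'   helix (default 17).
#' @param helix_bs_nt Intron nucleotides locked in the U2/BS helix
#'   (default 14).
#' @param gap_nm Distance between the two helices in the B complex, in nm
#'   (default 15).
#' @param rise_nm_per_nt Contour length of single-stranded RNA in an extended
#'   conformation, nm per nt (default 0.7).
#' @return A `geometry_model` object (a validated list).
#' @export
geometry_model <- function(helix_5ss_nt = 17, helix_bs_nt = 14,
                           gap_nm = 15, rise_nm_per_nt = 0.7) {
  if (rise_nm_per_nt <= 0) {
    stop("rise_nm_per_nt must be positive")
  }
  if (helix_5ss_nt < 0 || helix_bs_nt < 0 || gap_nm < 0) {
    stop("helix lengths and gap must be non-negative")
  }
  structure(
    list(helix_5ss_nt = helix_5ss_nt, helix_bs_nt = helix_bs_nt,
         gap_nm = gap_nm, rise_nm_per_nt = rise_nm_per_nt),
    class = "geometry_model"
  )
}

#' Nucleotides needed to span the inter-helix gap in extended conformation
#'
#' @param model A [geometry_model()].
#' @return Integer nt: `round(gap_nm / rise_nm_per_nt)`.  The default model
#'   gives 21 nt for the 15 nm gap.
#' @export
extended_span_nt <- function(model = geometry_model()) {
  round(model$gap_nm / model$rise_nm_per_nt)
}

#' Minimal 5'SS-to-BS span compatible with the B-complex geometry
#'
#' The two helices plus the fully extended single strand bridging them:
#' `helix_5ss_nt + extended_span_nt(model) + helix_bs_nt` (about 52 nt under
#' the default model), below which an intron cannot thread the complex
#' without distorting it.
#'
#' @param model A [geometry_model()].
#' @return Integer nt.
#' @export
min_span_nt <- function(model = geometry_model()) {
  model$helix_5ss_nt + extended_span_nt(model) + model$helix_bs_nt
}

#' 5'SS-BS distance of a truncated or extended splicing construct
#'
#' Construct series are built by removing or adding nucleotides strictly
#' between the 5'SS region and the BS region, so the BS-to-3'SS block of the
#' reference intron is conserved.  The new 5'SS-BS distance is therefore
#' `new_intron_len - (ref_intron_len - ref_distance)`.
#'
#' @param ref_intron_len Reference intron length (nt).
#' @param ref_distance Reference 5'SS-BS distance (nt).
#' @param new_intron_len New intron length (nt).  Vectorised.
#' @return The new 5'SS-BS distance (nt).  Errors when the new intron is too
#'   short to hold the conserved BS-to-3'SS block.
#' @examples
#' construct_distance(120, 96, c(150, 90, 80, 70))  # 126 66 56 46
#' @export
construct_distance <- function(ref_intron_len, ref_distance, new_intron_len) {
  conserved <- ref_intron_len - ref_distance
  if (any(new_intron_len <= conserved)) {
    stop("construct impossible: new intron length must exceed the conserved ",
         "BS-to-3'SS block (", conserved, " nt)")
  }
  new_intron_len - conserved
}
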