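# Ideal A-form RNA residue template.
#
# Base heavy atoms sit in the standard base-pair reference frame (planar,
# z = 0); the paired base of a Watson-Crick duplex is obtained by the frame
# flip (x, -y, -z). The sugar-phosphate moiety is a C3'-endo ribose
# (pseudorotation phase ~ 22 deg, amplitude ~ 34 deg) with an anti glycosidic
# torsion, positioned so that stacking residues along the helix
# (twist 32.7 deg / rise 2.81 A about an axis at x = -4.4 A in the pair
# frame) closes the backbone: |O3'(i) - P(i+1)| ~ 1.60 A on both strands.
# Coordinates were frozen from a one-off constrained least-squares fit of
# standard bond lengths, bond angles and A-form torsions.

.aform <- local({
  sugar <- matrix(c(
    -1.9598, 6.7109, -0.1737,
    -2.8122, 5.3707,  1.5052,
    -2.8946, 6.8317,  1.9695,
    -1.8869, 7.4648,  1.0494,
    -4.0070, 4.6393,  1.7374,
    -2.1800, 6.8294,  3.2138,
    -0.7310, 6.6143,  0.6495,
    -0.0745, 6.1591,  1.8317,
     1.3532, 5.5253,  1.6579,
     2.3350, 6.2435,  2.5097,
     1.6453, 5.3189,  0.2165), ncol = 3, byrow = TRUE)
  rownames(sugar) <- c("O4'", "C2'", "C3'", "C4'", "O2'", "O3'",
                       "C5'", "O5'", "P", "OP1", "OP2")
  bases <- list(
    A = matrix(c(
      -1.291, 4.498, 0,  0.024, 4.897, 0,  0.877, 3.902, 0,
       0.071, 2.771, 0,  0.369, 1.398, 0,  1.611, 0.909, 0,
      -0.668, 0.532, 0, -1.912, 1.023, 0, -2.320, 2.290, 0,
      -1.267, 3.124, 0), ncol = 3, byrow = TRUE,
      dimnames = list(c("N9", "C8", "N7", "C5", "C6", "N6",
                        "N1", "C2", "N3", "C4"), NULL)),
    G = matrix(c(
      -1.289, 4.551, 0,  0.023, 4.962, 0,  0.870, 3.969, 0,
       0.071, 2.833, 0,  0.424, 1.460, 0,  1.554, 0.955, 0,
      -0.700, 0.641, 0, -1.999, 1.087, 0, -2.949, 0.139, 0,
      -2.342, 2.364, 0, -1.265, 3.177, 0), ncol = 3, byrow = TRUE,
      dimnames = list(c("N9", "C8", "N7", "C5", "C6", "O6",
                        "N1", "C2", "N2", "N3", "C4"), NULL)),
    C = matrix(c(
      -1.285, 4.542, 0, -1.472, 3.158, 0, -2.628, 2.709, 0,
      -0.391, 2.344, 0,  0.837, 2.868, 0,  1.875, 2.027, 0,
       1.056, 4.275, 0, -0.023, 5.068, 0), ncol = 3, byrow = TRUE,
      dimnames = list(c("N1", "C2", "O2", "N3", "C4", "N4",
                        "C5", "C6"), NULL)),
    U = matrix(c(
      -1.284, 4.500, 0, -1.462, 3.131, 0, -2.563, 2.608, 0,
      -0.302, 2.397, 0,  0.989, 2.884, 0,  1.935, 2.094, 0,
       1.089, 4.311, 0, -0.024, 5.053, 0), ncol = 3, byrow = TRUE,
      dimnames = list(c("N1", "C2", "O2", "N3", "C4", "O4",
                        "C5", "C6"), NULL))
  )
  list(
    c1p = c(-2.477, 5.399, 0),
    sugar = sugar,
    bases = bases,
    dx = -4.4,
    twist = 32.7,
    rise = 2.81
  )
})
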