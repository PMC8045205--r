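# Published rectum-constraint values frozen for golden tests.
# Doses in Gy (RBE); differences in percent.

PUB <- list(
  nirs_mkm_16fx = c(28.80, 46.40, 56.00, 60.80),      # D20/10/5/0 %
  lem_16fx      = c(43.14, 58.48, 65.11, 68.33),      # same, after RBE conv.
  cnao_lem_16fx = c(54.00, 61.00, 66.00),             # D10/5/1 cc
  cnao_mkm_back = c(39.99, 49.84, 57.31),             # backward-converted
  # LEM LQ cells (percentage-volume rows then absolute-volume rows)
  lem_lq = list(
    `12` = list(pct = c(39.55, 53.08, 58.91, 61.73),
                cc  = c(49.14, 55.30, 59.69)),
    `8`  = list(pct = c(34.60, 45.86, 50.69, 53.03),
                cc  = c(42.59, 47.70, 51.33)),
    `4`  = list(pct = c(26.83, 34.96, 38.42, 40.10),
                cc  = c(32.60, 36.28, 38.88))),
  # MKM LQ cells (reproduced anchor-exactly by the reconstructed curves)
  mkm_lq = list(
    `12` = list(pct = c(37.60, 49.74, 55.27, 58.01),
                cc  = c(45.97, 51.70, 55.97)),
    `8`  = list(pct = c(30.40, 39.25, 43.41, 45.46),
                cc  = c(36.53, 40.73, 43.97)),
    `4`  = list(pct = c(20.80, 25.66, 28.33, 29.64),
                cc  = c(23.94, 26.62, 28.67))),
  # printed difference percentages for the absolute-volume table
  diff_cc = list(`12` = c(6.90, 6.96, 6.65),
                 `8`  = c(16.58, 17.12, 16.75),
                 `4`  = c(36.19, 36.30, 35.59)))
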