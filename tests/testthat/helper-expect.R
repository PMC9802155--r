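# absolute comparison at the precision a table prints (half a unit in the
# last printed digit, plus float slack)
expect_printed <- function(actual, printed, digits) {
  expect_lt(abs(actual - printed), 0.51 * 10^(-digits))
}
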