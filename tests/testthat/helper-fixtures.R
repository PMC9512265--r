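# Small shared fixtures for the test suite.

tiny_params <- function(...) model_params(N = 8, lambda_asym = 24, ...)

# a hand-built event log: individual A fights and antennates over 2 h
toy_log <- function() {
  event_log(
    time_h = c(0.1, 0.1, 0.3, 0.3, 0.5, 0.5, 0.7, 0.7, seq(0.9, 1.5, by = 0.2)),
    actor = c("A", "B", "A", "C", "A", "B", "B", "A", "A", "A", "A", "A"),
    recipient = c("B", "A", "C", "A", "B", "A", "A", "B", "B", "C", "B", "C"),
    type = c("DOM", "SUB", "DOM", "SUB", "DOM", "SUB", "DOM", "SUB",
             "ANT", "ANT", "ANT", "ANT"),
    phase = "control")
}
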