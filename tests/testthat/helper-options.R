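# report every expectation failure instead of aborting the run part-way:
# the biomarker-reproduction block intentionally asserts many published
# values and must not starve the remaining test files
options(testthat.progress.max_fails = 1e6)
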