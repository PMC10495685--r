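# stop the background LP worker when the suite finishes
withr::defer(lp_worker_stop(), teardown_env())
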