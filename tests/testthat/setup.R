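# Single-threaded BLAS: the small-matrix workloads lose badly to thread
# spinning, and results are independent of thread count.
Sys.setenv(OPENBLAS_NUM_THREADS = "1", OMP_NUM_THREADS = "1")
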