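modality,n_acquired,n_qc
T1,294,167
DTI,294,167
DaTSCAN,294,167
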