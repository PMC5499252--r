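dwt_oracle_*.csv: independent oracle for the single-level separable DWT.
Input: 32x32 standard-normal draw (numpy default_rng(20240917), rounded to
6 decimals).  Expected subbands computed with PyWavelets (pywt.dwt2,
mode="periodization") using a custom wavelet whose filter bank is the
package's tree-A Q-shift pair (dec_lo = qshift_low_a, dec_hi =
qshift_high_a, rec_* their time-reverses).  Subband names follow the same
(LL, LH, HL, HH) convention as dwt_analysis_level().
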