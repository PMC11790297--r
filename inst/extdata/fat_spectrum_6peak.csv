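# Six-peak triglyceride 1H spectral model: chemical shift (ppm) and
# relative amplitude (amplitudes sum to 1). Water reference 4.7 ppm.
ppm,amplitude
5.30,0.047
4.20,0.039
2.76,0.006
2.10,0.120
1.30,0.700
0.90,0.088
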