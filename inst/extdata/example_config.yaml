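# Example configuration: the published parameter table with the original
# price read as $100,000 per two months instead of the $80,000 annual
# treatment expense (both readings appear in the source data; the package
# default is the annual expense). All omitted keys take the package defaults.
p_orig: 600000.0
phi: 0.625
morbidity: 3.0e-5
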