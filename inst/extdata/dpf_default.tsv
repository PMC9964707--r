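# Differential pathlength factors (dimensionless) for rat hindlimb tissue at the
# two analysis wavelengths, from the DPF literature for an 8 mm source-detector
# separation. Linear interpolation only between entries; never extrapolated.
# Columns: wavelength_nm<TAB>dpf
wavelength_nm	dpf
740	3.5
840	3.01
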