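# tiny MGF fixture: 3 spectra, reporter 126 present in spectra 1 and 3
BEGIN IONS
TITLE=spectrum_1
PEPMASS=650.32 12345.0
CHARGE=2+
110.0712 830.0
126.1277 15200.0
350.1702 920.5
END IONS
BEGIN IONS
TITLE=spectrum_2
PEPMASS=720.85 9876.0
CHARGE=2+
126.1400 4000.0
245.0881 300.2
610.3342 1250.0
END IONS
BEGIN IONS
TITLE=spectrum_3
PEPMASS=505.77 4567.0
CHARGE=3+
127.1247 8800.0
131.1381 6100.0
422.2405 710.0
END IONS
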