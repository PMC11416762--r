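V01	V02
V01	V03
V01	V07
V01	V09
V01	V10
V01	V12
V02	V05
V02	V06
V02	V07
V02	V08
V02	V09
V02	V10
V02	V12
V03	V09
V03	V12
V04	V06
V04	V08
V04	V10
V04	V12
V05	V06
V05	V10
V05	V11
V05	V12
V06	V07
V06	V08
V06	V12
V07	V09
V07	V11
V08	V09
V08	V10
V08	V11
V08	V12
V09	V12
V10	V12
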