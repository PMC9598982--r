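grade,label,area_km2,percent
1,very poor,7759.39,51.94
2,poor,506.31,3.08
3,medium,2534.52,15.13
4,good,2585.69,13.24
5,excellent,3038.35,16.60
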