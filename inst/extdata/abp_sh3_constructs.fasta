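>AbpSC Saccharomyces cerevisiae Abp1p SH3 construct with C-terminal His-tag
MAPKENPWATAEYDYDAAEDNELTFVENDKIINIEFVDDDWWLGELEKDGSKGLFPSNYVSLGNLEHHHHHH
>AbpBD Batrachochytrium dendrobatidis Abp1p SH3 construct with C-terminal His-tag
MGYREATAVYDYVAAEPNELSFNEGNLITHIVFVSEDWWQGTLNGVVGLFPGNYVELKQLEHHHHHH
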