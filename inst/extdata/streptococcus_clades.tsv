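species	clade
Streptococcus sanguinis	Sanguinis
Streptococcus gordonii	Sanguinis
Streptococcus cristatus	Sanguinis
Streptococcus sinensis	Sanguinis
Streptococcus mitis	Mitis
Streptococcus oralis	Mitis
Streptococcus oralis_S	Mitis
Streptococcus pneumoniae	Mitis
Streptococcus pseudopneumoniae	Mitis
Streptococcus infantis	Mitis
Streptococcus lactarius	Mitis
Streptococcus parasanguinis	Mitis
Streptococcus australis	Mitis
Streptococcus peroris	Mitis
Streptococcus salivarius	Salivarius
Streptococcus vestibularis	Salivarius
Streptococcus thermophilus	Salivarius
Streptococcus anginosus	Anginosus
Streptococcus constellatus	Anginosus
Streptococcus intermedius	Anginosus
Streptococcus equinus	Bovis
Streptococcus gallolyticus	Bovis
Streptococcus infantarius	Bovis
Streptococcus alactolyticus	Bovis
Streptococcus pyogenes	Pyogenic
Streptococcus agalactiae	Pyogenic
Streptococcus dysgalactiae	Pyogenic
Streptococcus uberis	Pyogenic
Streptococcus canis	Pyogenic
Streptococcus iniae	Pyogenic
Streptococcus mutans	Mutans
Streptococcus sobrinus	Mutans
Streptococcus ratti	Mutans
Streptococcus macacae	Mutans
Streptococcus downei	Downei
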