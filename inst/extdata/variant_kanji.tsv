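char	variants
斎	斉,齋,齊
斉	斎,齊
沢	澤
高	髙
浜	濱
辺	邊,邉
島	嶋
崎	﨑,嵜
国	國
円	圓
広	廣
竜	龍
万	萬
桜	櫻
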