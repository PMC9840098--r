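kanji	kana	sex
太郎	タロウ	M
健一	ケンイチ	M
誠	マコト	M
浩	ヒロシ	M
隆	タカシ	M
学	マナブ	M
修	オサム	M
聡	サトシ	M
健太	ケンタ	M
大輔	ダイスケ	M
直樹	ナオキ	M
和也	カズヤ	M
翔太	ショウタ	M
拓也	タクヤ	M
亮	リョウ	M
徹	トオル	M
勇	イサム	M
茂	シゲル	M
秀樹	ヒデキ	M
正雄	マサオ	M
博	ヒロシ	M
信夫	ノブオ	M
義男	ヨシオ	M
清	キヨシ	M
進	ススム	M
花子	ハナコ	F
幸子	サチコ	F
美咲	ミサキ	F
陽子	ヨウコ	F
恵子	ケイコ	F
由美	ユミ	F
直美	ナオミ	F
真由美	マユミ	F
久美子	クミコ	F
裕子	ユウコ	F
典子	ノリコ	F
智子	トモコ	F
愛	アイ	F
舞	マイ	F
彩	アヤ	F
葵	アオイ	F
結衣	ユイ	F
陽菜	ヒナ	F
美穂	ミホ	F
香織	カオリ	F
綾子	アヤコ	F
千代	チヨ	F
和子	カズコ	F
洋子	ヨウコ	F
京子	キョウコ	F
明美	アケミ	F
優子	ユウコ	F
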