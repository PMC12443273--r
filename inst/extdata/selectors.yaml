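# Per-platform CSS selector configuration for saved comment-section HTML.
# Each block maps the four scraped fields to selectors inside one comment
# container element.
facebook:
  comment_container_selector: "div.comment-block"
  field_selectors:
    name: "span.comment-author"
    comment: "div.comment-text"
    likes: "span.comment-likes"
    replies: "span.comment-replies"
reddit:
  comment_container_selector: "div.reddit-comment"
  field_selectors:
    name: "a.author-link"
    comment: "p.comment-body"
    likes: "span.score"
    replies: "span.reply-count"
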